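# Programmatic fixtures: small record sets and grids built in code.

make_records <- function(n = 1, species = "O_lurida", abundance = "common",
                         year = 2010L, x = 1000, y = 1000,
                         substrate = "riprap_boulder", source = "published",
                         estuary_id = NA_character_, region = NA_character_,
                         sensitive = FALSE, id_prefix = "T") {
  tibble::tibble(
    record_id = sprintf("%s%03d", id_prefix, seq_len(n)),
    species = rep_len(species, n),
    x = rep_len(x, n), y = rep_len(y, n),
    lon = NA_real_, lat = NA_real_,
    year = as.integer(rep_len(year, n)),
    abundance_class = rep_len(abundance, n),
    substrate_class = rep_len(substrate, n),
    source_type = rep_len(source, n),
    estuary_id = rep_len(estuary_id, n),
    region = rep_len(region, n),
    sensitive = rep_len(sensitive, n)
  )
}

# records laid out as an abundance-class mixture for one estuary cell
mix_records <- function(common = 0, rare = 0, present = 0, absent = 0, ...) {
  make_records(n = common + rare + present + absent,
               abundance = rep(c("common", "rare", "present_unknown", "absent"),
                               c(common, rare, present, absent)), ...)
}

# an all-water grid of given physical size
open_grid <- function(width, height, cell, connectivity = 16) {
  rasterize_coast(list(), c(0, 0, width, height), cell,
                  connectivity = connectivity)
}

# random barrier grid: water with rectangular land blocks dropped in
random_barrier_grid <- function(nr, nc, cell, n_blocks = 4, connectivity = 16) {
  land <- lapply(seq_len(n_blocks), function(i) {
    w <- sample.int(max(2, nc %/% 3), 1) * cell
    h <- sample.int(max(2, nr %/% 3), 1) * cell
    x0 <- runif(1, 0, nc * cell - w)
    y0 <- runif(1, 0, nr * cell - h)
    list(rect_ring(x0, y0, x0 + w, y0 + h))
  })
  tryCatch(
    rasterize_coast(land, c(0, 0, nc * cell, nr * cell), cell,
                    connectivity = connectivity),
    error = function(e) open_grid(nc * cell, nr * cell, cell, connectivity)
  )
}

# a random water cell (row, col)
random_water_cell <- function(grid) {
  w <- which(grid$water, arr.ind = TRUE)
  w[sample.int(nrow(w), 1), ]
}
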