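# Synthetic coastlines and oyster records with known ground truth.
#
# Scenarios are minimal planar geometries (coast running along x, water
# above a land band) that exercise the pipeline: an open water strip, a
# peninsula barrier forcing an along-water detour, an archipelago with
# widely separated planted record clusters, and a chain of estuaries. The
# generator emulates the record schema, the abundance-class mixture, the
# pre-2000 vs post-2000 structure (native decline, non-native increase), and
# regional substrate mixtures; every record carries a ground-truth entry.

.default_substrate_mix <- rbind(
  North = c(riprap_boulder = 0.10, cobble = 0.15, gravel_pebble = 0.20,
            sandflat_mudflat = 0.40, seawall_dock_piling = 0.10,
            other_anthropogenic = 0.05),
  Central = c(0.20, 0.15, 0.20, 0.25, 0.15, 0.05),
  South = c(0.40, 0.10, 0.10, 0.10, 0.25, 0.05)
)
colnames(.default_substrate_mix) <- substrate_classes

#' Configure a synthetic scenario
#'
#' Defaults encode the study conditions the package is validated against:
#' 20 estuaries with 12 records per estuary x species x period, a native
#' species starting common and widespread (presence probability 0.8,
#' common-given-abundance fraction 0.6) that declines by 0.3 after 2000, a
#' non-native starting sparse (0.3) that increases by 0.3, a tenth of
#' presence records carrying no abundance information, and regional
#' substrate mixtures grading from soft natural substrates in the north to
#' riprap and other anthropogenic structure in the south.
#'
#' @param seed Integer seed; the whole generation is a deterministic
#'   function of the config including the seed.
#' @param scenario `"open_strip"`, `"spit_barrier"`, `"archipelago"`, or
#'   `"estuary_chain"`.
#' @param n_estuaries Number of estuary polygons along the shore.
#' @param n_records_per_period Records drawn per estuary x species x period.
#' @param theta_pre Named (by species) pre-2000 presence probabilities.
#' @param delta Named additive change in presence probability post-2000.
#' @param phi Named probability that an abundance-informative presence
#'   record is "common" (vs "rare").
#' @param punknown_frac Fraction of presence records entered as present with
#'   unknown abundance.
#' @param theta_jitter Half-width of the uniform per-estuary jitter on
#'   `theta_pre` (estuary heterogeneity; set 0 to plant exact values).
#' @param substrate_mix 3 x 6 matrix of substrate probabilities with rows
#'   `North`, `Central`, `South`.
#' @param cell_size Grid cell size in meters (scenario-scaled default).
#' @param sensitive_frac Fraction of records flagged sensitive.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(seed = 1,
                            scenario = c("open_strip", "spit_barrier",
                                         "archipelago", "estuary_chain"),
                            n_estuaries = NULL,
                            n_records_per_period = 12,
                            theta_pre = c(O_lurida = 0.8, M_gigas = 0.3),
                            delta = c(O_lurida = -0.3, M_gigas = 0.3),
                            phi = c(O_lurida = 0.6, M_gigas = 0.5),
                            punknown_frac = 0.1,
                            theta_jitter = 0.1,
                            substrate_mix = .default_substrate_mix,
                            cell_size = NULL,
                            sensitive_frac = 0.05) {
  scenario <- match.arg(scenario)
  geom <- switch(scenario,
    open_strip = list(extent_x = 100e3, extent_y = 30e3, cell = 250,
                      n_est = 20),
    spit_barrier = list(extent_x = 100e3, extent_y = 40e3, cell = 250,
                        n_est = 0),
    archipelago = list(extent_x = 200e3, extent_y = 80e3, cell = 500,
                       n_est = 0),
    estuary_chain = list(extent_x = 160e3, extent_y = 40e3, cell = 400,
                         n_est = 8)
  )
  n_estuaries <- n_estuaries %||% geom$n_est
  cell_size <- cell_size %||% geom$cell
  stopifnot(all(theta_pre >= 0 & theta_pre <= 1),
            all(theta_pre + delta >= 0 & theta_pre + delta <= 1),
            all(phi >= 0 & phi <= 1),
            all(abs(rowSums(substrate_mix) - 1) < 1e-9))
  structure(list(
    seed = as.integer(seed), scenario = scenario,
    extent_x = geom$extent_x, extent_y = geom$extent_y,
    cell_size = cell_size, n_estuaries = n_estuaries,
    n_records_per_period = n_records_per_period,
    theta_pre = theta_pre, delta = delta, phi = phi,
    punknown_frac = punknown_frac, theta_jitter = theta_jitter,
    substrate_mix = substrate_mix, sensitive_frac = sensitive_frac
  ), class = "scenario_config")
}

# alongshore thirds -> state/province labels (one per broad region)
.region_of_x <- function(x, extent_x) {
  dplyr::case_when(
    x < extent_x / 3 ~ "Washington",
    x < 2 * extent_x / 3 ~ "NorthernCalifornia",
    TRUE ~ "SouthernCalifornia"
  )
}

#' Generate the scenario coastline
#'
#' Deterministic geometry per config: a land band along the bottom of the
#' extent, scenario-specific barriers (peninsula, islands), estuary polygons
#' embedded in the water, and, for the barrier scenarios, planted record
#' clusters whose network membership is known by construction (intra-cluster
#' along-water gaps far below the linkage distance, inter-cluster gaps far
#' above it).
#'
#' @param cfg A [scenario_config()].
#' @return List: `land` (list of polygons), `estuaries` (tibble from
#'   [estuary_set()]), `extent`, `clusters` (tibble of planted clusters:
#'   `cluster_id`, `network_label`, `x`, `y`, `radius`, `n_records`,
#'   `region`), and for `spit_barrier` the pair `detour_points` whose
#'   straight-line and along-water distances differ by the planted detour.
#' @export
make_coastline <- function(cfg) {
  ex <- cfg$extent_x; ey <- cfg$extent_y
  shore <- 5e3
  land <- list(list(rect_ring(0, 0, ex, shore)))
  clusters <- tibble::tibble(cluster_id = character(), network_label = integer(),
                             x = numeric(), y = numeric(), radius = numeric(),
                             n_records = integer(), region = character())
  detour_points <- NULL
  if (cfg$scenario == "spit_barrier") {
    land <- c(land, list(list(rect_ring(ex / 2 - 1e3, shore - 100, ex / 2 + 1e3,
                                        ey - 4e3))))
    pts <- rbind(c(ex / 2 - 6e3, 8e3), c(ex / 2 + 6e3, 8e3))
    detour_points <- pts
    clusters <- tibble::tibble(
      cluster_id = c("C1", "C2"), network_label = c(1L, 2L),
      x = pts[, 1], y = pts[, 2], radius = 2e3,
      n_records = cfg$n_records_per_period,
      region = .region_of_x(pts[, 1], ex)
    )
  } else if (cfg$scenario == "archipelago") {
    island <- function(cx, cy, half) list(rect_ring(cx - half, cy - half,
                                                    cx + half, cy + half))
    land <- c(land,
              list(island(65e3, 40e3, 4e3)), list(island(135e3, 40e3, 4e3)),
              list(island(65e3, 15e3, 3e3)), list(island(135e3, 65e3, 3e3)),
              list(island(100e3, 12e3, 3e3)))
    cx <- c(30e3, 100e3, 170e3)
    clusters <- tibble::tibble(
      cluster_id = paste0("C", 1:3), network_label = 1:3,
      x = cx, y = rep(40e3, 3), radius = 4e3,
      n_records = cfg$n_records_per_period,
      region = .region_of_x(cx, ex)
    )
  }
  estuaries <- if (cfg$n_estuaries > 0) {
    w <- 3e3; h <- 4e3
    centers <- seq(ex / (cfg$n_estuaries + 1), ex - ex / (cfg$n_estuaries + 1),
                   length.out = cfg$n_estuaries)
    estuary_set(
      estuary_id = sprintf("E%02d", seq_len(cfg$n_estuaries)),
      polygon = purrr::map(centers, ~ rect_ring(.x - w / 2, shore, .x + w / 2,
                                                shore + h)),
      region = .region_of_x(centers, ex)
    )
  } else {
    estuary_set(character(0), list(), character(0))
  }
  list(land = land, estuaries = estuaries,
       extent = c(0, 0, ex, ey), clusters = clusters,
       detour_points = detour_points)
}

.sample_in_polygon <- function(n, poly, grid, max_tries = 200) {
  bb <- poly_bbox(poly)
  out <- matrix(NA_real_, n, 2)
  got <- 0
  for (t in seq_len(max_tries)) {
    if (got >= n) break
    m <- (n - got) * 2 + 8
    px <- stats::runif(m, bb["xmin"], bb["xmax"])
    py <- stats::runif(m, bb["ymin"], bb["ymax"])
    ok <- poly_contains(poly, px, py)
    rc <- grid_rowcol(grid, px, py)
    ok <- ok & grid$water[cbind(rc[, "row"], rc[, "col"])]
    take <- min(sum(ok), n - got)
    if (take > 0) {
      idx <- which(ok)[seq_len(take)]
      out[(got + 1):(got + take), ] <- cbind(px[idx], py[idx])
      got <- got + take
    }
  }
  if (got < n) stop("could not place records on water inside the polygon")
  out
}

.sample_in_disk <- function(n, cx, cy, radius, grid, max_tries = 200) {
  out <- matrix(NA_real_, n, 2)
  got <- 0
  for (t in seq_len(max_tries)) {
    if (got >= n) break
    m <- (n - got) * 2 + 8
    r <- radius * sqrt(stats::runif(m))
    a <- stats::runif(m, 0, 2 * pi)
    px <- cx + r * cos(a); py <- cy + r * sin(a)
    rc <- grid_rowcol(grid, px, py)
    ok <- grid$water[cbind(rc[, "row"], rc[, "col"])] &
      px > 0 & py > 0
    take <- min(sum(ok), n - got)
    if (take > 0) {
      idx <- which(ok)[seq_len(take)]
      out[(got + 1):(got + take), ] <- cbind(px[idx], py[idx])
      got <- got + take
    }
  }
  if (got < n) stop("cluster centered on land with no nearby water")
  out
}

.draw_abundance <- function(n, theta, phi, punknown) {
  present <- stats::runif(n) < theta
  cls <- rep("absent", n)
  if (any(present)) {
    unk <- present & stats::runif(n) < punknown
    common <- present & !unk & stats::runif(n) < phi
    cls[unk] <- "present_unknown"
    cls[common] <- "common"
    cls[present & !unk & !common] <- "rare"
  }
  cls
}

#' Simulate oyster records with ground truth
#'
#' Draws records deterministically from the scenario config: for each
#' estuary x species x period, `n_records_per_period` records whose presence
#' probability is the planted theta (plus delta after 2000), with
#' abundance-informative presence records common with probability phi,
#' substrates drawn from the regional multinomial, and locations on water
#' inside the estuary. Planted barrier-scenario clusters additionally
#' generate current-period presence records of the native species with known
#' network membership.
#'
#' @param cfg A [scenario_config()].
#' @param coast Optional pre-built coastline from [make_coastline()].
#' @param grid Optional pre-built grid from [rasterize_coast()].
#' @return List: `records` (record tibble with `region` joined), `truth`
#'   (ground-truth tables: `records`, `estuaries`, `regions`), `coast`,
#'   `grid`.
#' @export
simulate_records <- function(cfg, coast = NULL, grid = NULL) {
  coast <- coast %||% make_coastline(cfg)
  grid <- grid %||% rasterize_coast(coast$land, coast$extent, cfg$cell_size)
  species <- names(cfg$theta_pre)
  withr::with_seed(cfg$seed, {
    rows <- list()
    truth_rows <- list()
    truth_est <- list()
    next_id <- 1L
    emit <- function(n, sp, cls, x, y, years, region, cluster_id, label,
                     estuary_id, theta, phi) {
      ids <- sprintf("R%05d", next_id:(next_id + n - 1L))
      next_id <<- next_id + n
      mix <- cfg$substrate_mix[region_broad(region), ]
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        record_id = ids, species = sp, x = x, y = y,
        lon = NA_real_, lat = NA_real_, year = years,
        abundance_class = cls,
        substrate_class = sample(substrate_classes, n, replace = TRUE, prob = mix),
        source_type = sample(source_types, n, replace = TRUE,
                             prob = c(0.4, 0.4, 0.2)),
        estuary_id = estuary_id, region = region,
        sensitive = stats::runif(n) < cfg$sensitive_frac
      )
      truth_rows[[length(truth_rows) + 1L]] <<- tibble::tibble(
        record_id = ids, cluster_id = cluster_id, network_label = label,
        estuary_id = estuary_id, species = sp, theta = theta, phi = phi,
        region = region
      )
    }

    est <- coast$estuaries
    for (e in seq_len(nrow(est))) {
      for (sp in species) {
        jit <- stats::runif(1, -cfg$theta_jitter, cfg$theta_jitter)
        th_pre <- min(1, max(0, cfg$theta_pre[[sp]] + jit))
        th_post <- min(1, max(0, th_pre + cfg$delta[[sp]]))
        truth_est[[length(truth_est) + 1L]] <- tibble::tibble(
          estuary_id = est$estuary_id[e], species = sp,
          theta_pre = th_pre, theta_post = th_post, phi = cfg$phi[[sp]]
        )
        for (per in c("pre2000", "post2000")) {
          n <- cfg$n_records_per_period
          if (n == 0) next
          th <- if (per == "pre2000") th_pre else th_post
          cls <- .draw_abundance(n, th, cfg$phi[[sp]], cfg$punknown_frac)
          xy <- .sample_in_polygon(n, est$polygon[[e]], grid)
          years <- if (per == "pre2000") sample(1950:1999, n, replace = TRUE)
                   else sample(2000:2020, n, replace = TRUE)
          emit(n, sp, cls, xy[, 1], xy[, 2], years, est$region[e],
               NA_character_, NA_integer_, est$estuary_id[e], th, cfg$phi[[sp]])
        }
      }
    }

    cl <- coast$clusters
    for (k in seq_len(nrow(cl))) {
      n <- cl$n_records[k]
      xy <- .sample_in_disk(n, cl$x[k], cl$y[k], cl$radius[k], grid)
      phi_o <- cfg$phi[["O_lurida"]]
      cls <- ifelse(stats::runif(n) < phi_o, "common", "rare")
      emit(n, "O_lurida", cls, xy[, 1], xy[, 2],
           sample(2000:2020, n, replace = TRUE), cl$region[k],
           cl$cluster_id[k], cl$network_label[k], NA_character_, 1, phi_o)
    }

    records <- dplyr::bind_rows(rows)
    truth <- list(
      records = dplyr::bind_rows(truth_rows),
      estuaries = dplyr::bind_rows(truth_est),
      regions = tibble::as_tibble(cfg$substrate_mix, rownames = "region")
    )
    list(records = records, truth = truth, coast = coast, grid = grid)
  })
}

#' Write and read ground-truth tables
#'
#' @param truth The `truth` list from [simulate_records()].
#' @param dir Output directory (created if needed).
#' @return `export_ground_truth()`: the written paths, invisibly.
#'   `read_ground_truth()`: the truth list.
#' @export
export_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    records = file.path(dir, "truth_records.csv"),
    estuaries = file.path(dir, "truth_estuaries.csv"),
    regions = file.path(dir, "truth_regions.csv")
  )
  readr::write_csv(truth$records, paths["records"], na = "")
  readr::write_csv(truth$estuaries, paths["estuaries"], na = "")
  readr::write_csv(truth$regions, paths["regions"], na = "")
  invisible(paths)
}

#' @rdname export_ground_truth
#' @export
read_ground_truth <- function(dir) {
  list(
    records = readr::read_csv(file.path(dir, "truth_records.csv"),
                              show_col_types = FALSE,
                              col_types = readr::cols(
                                record_id = "c", cluster_id = "c",
                                network_label = "i", estuary_id = "c",
                                species = "c", theta = "d", phi = "d",
                                region = "c")),
    estuaries = readr::read_csv(file.path(dir, "truth_estuaries.csv"),
                                show_col_types = FALSE),
    regions = readr::read_csv(file.path(dir, "truth_regions.csv"),
                              show_col_types = FALSE)
  )
}

#' Write a full scenario bundle to disk
#'
#' Emits the same file dialects the readers consume: the record CSV, land
#' and estuary GeoJSON, ground-truth CSVs, and a JSON echo of the config.
#'
#' @param cfg A [scenario_config()].
#' @param dir Output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
simulate_scenario <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_records(cfg)
  rec_path <- file.path(dir, "records.csv")
  write_records(dplyr::select(sim$records, -"region"), rec_path)
  land_path <- file.path(dir, "land.geojson")
  write_geojson_polygons(
    tibble::tibble(id = sprintf("L%d", seq_along(sim$coast$land)),
                   polygon = sim$coast$land),
    land_path)
  est_path <- file.path(dir, "estuaries.geojson")
  write_geojson_polygons(
    dplyr::select(sim$coast$estuaries, "estuary_id", "region", "polygon"),
    est_path)
  truth_paths <- export_ground_truth(sim$truth, dir)
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(
    c(cfg[c("seed", "scenario", "extent_x", "extent_y", "cell_size",
            "n_estuaries", "n_records_per_period", "punknown_frac",
            "theta_jitter", "sensitive_frac")],
      list(theta_pre = as.list(cfg$theta_pre), delta = as.list(cfg$delta),
           phi = as.list(cfg$phi))),
    cfg_path, auto_unbox = TRUE, digits = NA)
  invisible(c(records = rec_path, land = land_path, estuaries = est_path,
              truth_paths, config = cfg_path))
}
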