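# Larval and adult dispersal networks.
#
# Sites with living oysters observed in the current window (2000-2020) and
# within d_link along-water of each other belong to the same larval network
# (connected components of the linkage graph). Each network's polygon is the
# union of its members' d_max reachable water zones; the adult network is
# the part of that polygon inside estuary boundaries, where adults can
# actually live. Networks are numbered north to south by centroid northing,
# e.g. O-1, O-2 for the native species and M-1, ... for the non-native.

.species_letter <- c(O_lurida = "O", M_gigas = "M")

#' Build larval dispersal networks
#'
#' Uses only presence records (common, rare, or present with unknown
#' abundance) observed 2000-2020. Records are linked when their along-water
#' distance is at most `cfg$d_link`; networks are the connected components of
#' that linkage with at least `cfg$min_members` member records. Components
#' below the member threshold are reported as unassigned, as are isolated
#' records.
#'
#' @param records Record tibble, already snapped to the water grid (see
#'   [snap_to_water()]).
#' @param grid A `coast_grid`.
#' @param cfg A [network_config()].
#' @return A list with `networks` (tibble: `network_id`, `species`,
#'   `n_members`, `area_km2`, `centroid_x`, `centroid_y`, plus `mask` and
#'   `polygon` list-columns for the reachable-zone geometry), `membership`
#'   (tibble `record_id` -> `network_id`), and `unassigned` (record ids in
#'   components smaller than `min_members`).
#' @export
build_larval_networks <- function(records, grid, cfg = network_config()) {
  eligible <- records %>%
    dplyr::filter(.data$abundance_class %in% presence_classes,
                  assign_period(.data$year) %in% "post2000")
  if (nrow(eligible) == 0) stop("build_larval_networks: no eligible records")

  out_networks <- list()
  membership <- list()
  unassigned <- character(0)

  for (sp in unique(eligible$species)) {
    sub <- dplyr::filter(eligible, .data$species == sp)
    cells <- grid_cell_index(grid, sub$x, sub$y)
    ucells <- unique(cells)
    m <- length(ucells)
    # linkage graph over distinct occupied cells
    adj <- matrix(FALSE, m, m)
    for (i in seq_len(m)) {
      d <- water_distance(grid, ucells[i], d_max = cfg$d_link)
      adj[i, ] <- d[ucells] <= cfg$d_link
    }
    g <- igraph::graph_from_adjacency_matrix(adj | t(adj), mode = "undirected")
    comp <- igraph::components(g)$membership
    rec_comp <- comp[match(cells, ucells)]

    comp_sizes <- table(rec_comp)
    keep <- as.integer(names(comp_sizes)[comp_sizes >= cfg$min_members])
    unassigned <- c(unassigned, sub$record_id[!rec_comp %in% keep])

    nets <- purrr::map(keep, function(k) {
      members <- sub$record_id[rec_comp == k]
      src <- ucells[comp == k]
      dist <- water_distance(grid, src, d_max = cfg$d_max)
      mask <- is.finite(dist)
      idx <- which(mask)
      centers <- grid_cell_center(grid, idx)
      list(species = sp, members = members, mask = mask,
           area_km2 = length(idx) * grid$cell_size^2 / 1e6,
           centroid_x = mean(centers[, "x"]),
           centroid_y = mean(centers[, "y"]))
    })
    # number north -> south by centroid northing
    ord <- order(vapply(nets, `[[`, numeric(1), "centroid_y"), decreasing = TRUE)
    letter <- .species_letter[[sp]] %||% substr(sp, 1, 1)
    for (rank in seq_along(ord)) {
      net <- nets[[ord[rank]]]
      id <- sprintf("%s-%d", letter, rank)
      out_networks[[id]] <- tibble::tibble(
        network_id = id, species = sp, n_members = length(net$members),
        area_km2 = net$area_km2, centroid_x = net$centroid_x,
        centroid_y = net$centroid_y, mask = list(net$mask),
        polygon = list(mask_to_polygons(net$mask, grid))
      )
      membership[[id]] <- tibble::tibble(record_id = net$members, network_id = id)
    }
  }
  if (length(unassigned) > 0) {
    message(sprintf("build_larval_networks: %d record(s) in components below min_members left unassigned",
                    length(unassigned)))
  }
  list(networks = dplyr::bind_rows(out_networks),
       membership = dplyr::bind_rows(membership),
       unassigned = unassigned)
}

#' Clip larval networks to estuary boundaries
#'
#' The adult network is the portion of each larval network's reachable zone
#' that falls inside estuary polygons (open-ocean water is removed). Empty
#' intersections are reported with zero area.
#'
#' @param networks The `networks` tibble from [build_larval_networks()].
#' @param estuaries Estuary tibble from [estuary_set()].
#' @param grid The `coast_grid` the networks were built on.
#' @return Tibble: `network_id`, `species`, `area_km2` (adult), `larval_area_km2`,
#'   and an adult `polygon` list-column.
#' @export
clip_to_estuaries <- function(networks, estuaries, grid) {
  # estuary membership of every cell center, computed once
  idx_all <- seq_len(grid$n_rows * grid$n_cols)
  centers <- grid_cell_center(grid, idx_all)
  in_est <- rep(FALSE, length(idx_all))
  for (p in estuaries$polygon) {
    in_est <- in_est | poly_contains(p, centers[, "x"], centers[, "y"])
  }
  est_mask <- matrix(in_est, grid$n_rows, grid$n_cols)
  purrr::map_dfr(seq_len(nrow(networks)), function(i) {
    adult <- networks$mask[[i]] & est_mask
    tibble::tibble(
      network_id = networks$network_id[i],
      species = networks$species[i],
      area_km2 = sum(adult) * grid$cell_size^2 / 1e6,
      larval_area_km2 = networks$area_km2[i],
      polygon = list(if (any(adult)) mask_to_polygons(adult, grid) else list())
    )
  })
}

#' Optimal along-water connections between networks
#'
#' For every pair of networks of the same species, the shortest along-water
#' distance between any cell of one network's polygon and any cell of the
#' other's (multi-source shortest path, no truncation). Touching or
#' overlapping polygons get distance 0; a network unreachable by water gets
#' `Inf`.
#'
#' @param networks The `networks` tibble from [build_larval_networks()].
#' @param grid The `coast_grid`.
#' @return Edge tibble: `network_a`, `network_b`, `species`, `distance_m`
#'   (symmetric; each unordered pair listed once).
#' @export
optimal_connections <- function(networks, grid) {
  if (nrow(networks) < 2) {
    return(tibble::tibble(network_a = character(), network_b = character(),
                          species = character(), distance_m = numeric()))
  }
  edges <- list()
  for (sp in unique(networks$species)) {
    nets <- dplyr::filter(networks, .data$species == sp)
    n <- nrow(nets)
    if (n < 2) next
    cell_sets <- purrr::map(nets$mask, which)
    for (i in seq_len(n - 1)) {
      d <- water_distance(grid, cell_sets[[i]], d_max = Inf)
      for (j in (i + 1):n) {
        dist_ij <- min(d[cell_sets[[j]]])
        edges[[length(edges) + 1]] <- tibble::tibble(
          network_a = nets$network_id[i], network_b = nets$network_id[j],
          species = sp, distance_m = dist_ij)
      }
    }
  }
  out <- dplyr::bind_rows(edges)
  if (nrow(out) == 0) {
    return(tibble::tibble(network_a = character(), network_b = character(),
                          species = character(), distance_m = numeric()))
  }
  if (any(!is.finite(out$distance_m))) {
    warning("optimal_connections: some networks are unreachable by water (Inf edges)")
  }
  out
}

#' Network isolation scores
#'
#' For each network, the mean along-water distance to the nearest network to
#' the north (centroid northing strictly greater) and the nearest to the
#' south; with neighbors on only one side, that single distance; with no
#' other network of the species, undefined. Higher values mean more isolated
#' networks.
#'
#' @param networks The `networks` tibble.
#' @param edges Connection edges from [optimal_connections()].
#' @return Tibble: `network_id`, `dist_north_m`, `dist_south_m`,
#'   `isolation_m`.
#' @export
isolation_metric <- function(networks, edges) {
  sym <- dplyr::bind_rows(
    dplyr::select(edges, from = "network_a", to = "network_b", "distance_m"),
    dplyr::select(edges, from = "network_b", to = "network_a", "distance_m")
  )
  purrr::map_dfr(seq_len(nrow(networks)), function(i) {
    me <- networks[i, ]
    others <- dplyr::filter(networks, .data$species == me$species,
                            .data$network_id != me$network_id)
    my_edges <- dplyr::filter(sym, .data$from == me$network_id)
    nearest <- function(ids) {
      d <- my_edges$distance_m[my_edges$to %in% ids]
      if (length(d) == 0) NA_real_ else min(d)
    }
    dn <- nearest(others$network_id[others$centroid_y > me$centroid_y])
    ds <- nearest(others$network_id[others$centroid_y < me$centroid_y])
    iso <- mean(c(dn, ds), na.rm = TRUE)
    tibble::tibble(network_id = me$network_id,
                   dist_north_m = dn, dist_south_m = ds,
                   isolation_m = ifelse(is.nan(iso), NA_real_, iso))
  })
}

#' Vectorize a cell mask into boundary polygons
#'
#' Traces the outer boundary of the union of mask cells as closed rings on
#' cell edges (no smoothing, so ring areas reproduce the mask cell count
#' exactly). At vertices where mask cells touch diagonally the tracer takes
#' the rightmost turn, keeping diagonal neighbors in separate rings.
#'
#' @param mask Logical matrix dimensioned like `grid$water`.
#' @param grid The `coast_grid` providing the cell geometry.
#' @return A list of ring matrices (planar meters).
#' @export
mask_to_polygons <- function(mask, grid) {
  cells <- which(mask, arr.ind = TRUE)
  if (nrow(cells) == 0) return(list())
  cs <- grid$cell_size
  ox <- unname(grid$origin["x"]); oy <- unname(grid$origin["y"])
  has <- function(r, c) {
    r >= 1 & r <= nrow(mask) & c >= 1 & c <= ncol(mask) & mask[cbind(pmax(1, pmin(nrow(mask), r)), pmax(1, pmin(ncol(mask), c)))]
  }
  # boundary edges as directed segments (interior on the left), keyed by
  # start vertex; vertices are integer (col, row) corner coordinates
  edges <- list()
  for (k in seq_len(nrow(cells))) {
    r <- cells[k, 1]; c <- cells[k, 2]
    ll <- c(c - 1, r - 1); lr <- c(c, r - 1); ur <- c(c, r); ul <- c(c - 1, r)
    if (!has(r - 1, c)) edges[[length(edges) + 1]] <- list(a = ll, b = lr)
    if (!has(r, c + 1)) edges[[length(edges) + 1]] <- list(a = lr, b = ur)
    if (!has(r + 1, c)) edges[[length(edges) + 1]] <- list(a = ur, b = ul)
    if (!has(r, c - 1)) edges[[length(edges) + 1]] <- list(a = ul, b = ll)
  }
  key <- function(v) paste(v[1], v[2])
  by_start <- split(seq_along(edges), vapply(edges, function(e) key(e$a), character(1)))
  used <- rep(FALSE, length(edges))
  rings <- list()
  for (start in seq_along(edges)) {
    if (used[start]) next
    ring <- list()
    e <- edges[[start]]
    used[start] <- TRUE
    repeat {
      ring[[length(ring) + 1]] <- e$a
      nxt_ids <- by_start[[key(e$b)]]
      nxt_ids <- nxt_ids[!used[nxt_ids]]
      if (length(nxt_ids) == 0) break
      if (length(nxt_ids) > 1) {
        # rightmost turn relative to the incoming direction
        din <- e$b - e$a
        turn <- vapply(nxt_ids, function(id) {
          dout <- edges[[id]]$b - edges[[id]]$a
          atan2(din[1] * dout[2] - din[2] * dout[1],
                din[1] * dout[1] + din[2] * dout[2])
        }, numeric(1))
        nxt_ids <- nxt_ids[which.min(turn)]
      }
      e <- edges[[nxt_ids[1]]]
      used[nxt_ids[1]] <- TRUE
    }
    m <- do.call(rbind, ring)
    rings[[length(rings) + 1]] <- cbind(x = ox + m[, 1] * cs, y = oy + m[, 2] * cs)
  }
  rings
}
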