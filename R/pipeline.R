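# End-to-end pipeline: records in, report bundle out.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage: %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full oyster analysis pipeline
#'
#' Validates records, assigns estuaries and regions, builds the database
#' summary, per-estuary index and change tables with paired Wilcoxon tests,
#' larval/adult networks with connectivity and isolation, and substrate
#' use (plus selection, when an availability profile is supplied), writing
#' every output table and layer under `out_dir` together with a JSON run
#' manifest echoing the configuration.
#'
#' @param records Record tibble (e.g. from [read_records()]) or a CSV path.
#' @param land List of land polygons or a GeoJSON path.
#' @param estuaries Estuary tibble from [estuary_set()] or a GeoJSON path
#'   with `estuary_id` and `region` properties.
#' @param out_dir Output directory (created if needed).
#' @param availability Optional [availability_profile()] for the selection
#'   analysis.
#' @param cfg A [network_config()].
#' @param cell_size Grid cell size in meters.
#' @param extent Optional `c(xmin, ymin, xmax, ymax)`; defaults to the
#'   record bounding box padded by `cfg$d_max`.
#' @param min_records Replicate filter for index analyses (default 3).
#' @param alpha Familywise alpha for the selection intervals.
#' @param seed Seed echoed to seeded stages (Monte Carlo Fisher test).
#' @return Invisibly, a list with every computed table (`summary`,
#'   `indices`, `changes`, `networks`, `adult_networks`, `connections`,
#'   `isolation`, `substrate`, `selection`, `manifest`).
#' @export
run_pipeline <- function(records, land, estuaries, out_dir,
                         availability = NULL, cfg = network_config(),
                         cell_size = 250, extent = NULL, min_records = 3,
                         alpha = 0.05, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(records)) records <- read_records(records)
  if (is.character(land)) land <- read_geojson_polygons(land)$polygon
  if (is.character(estuaries)) {
    gj <- read_geojson_polygons(estuaries)
    estuaries <- estuary_set(gj$estuary_id, gj$polygon, gj$region)
  }

  records <- .stage("classify", {
    assign_estuary(records, estuaries, max_assign_m = cfg$snap_max)
  })

  summary_tbl <- .stage("summarize", summarize_database(records))
  readr::write_csv(summary_tbl, file.path(out_dir, "database_summary.csv"), na = "")

  indices <- .stage("indices", {
    purrr::map_dfr(c("distribution", "abundance"), function(ix)
      purrr::map_dfr(c("pre2000", "post2000"), function(per)
        indices_by_estuary(records, ix, per, min_records = min_records)))
  })
  readr::write_csv(indices, file.path(out_dir, "indices.csv"), na = "")

  changes <- .stage("change", {
    grids <- tidyr::expand_grid(species = unique(records$species),
                                index_type = c("distribution", "abundance"))
    purrr::map2_dfr(grids$species, grids$index_type, function(sp, ix) {
      pre <- dplyr::filter(indices, .data$species == sp,
                           .data$index_type == ix, .data$period == "pre2000")
      post <- dplyr::filter(indices, .data$species == sp,
                            .data$index_type == ix, .data$period == "post2000")
      ch <- paired_change(pre, post, min_records = min_records)
      dplyr::mutate(glance(ch), species = sp, index_type = ix,
                    .before = 1)
    })
  })
  readr::write_csv(changes, file.path(out_dir, "index_change.csv"), na = "")

  grid <- .stage("rasterize", {
    extent <- extent %||% c(min(records$x) - cfg$d_max, min(records$y) - cfg$d_max,
                            max(records$x) + cfg$d_max, max(records$y) + cfg$d_max)
    rasterize_coast(land, extent, cell_size, connectivity = cfg$connectivity)
  })

  net <- .stage("networks", {
    snapped <- snap_to_water(records, grid, cfg$snap_max)
    build_larval_networks(snapped, grid, cfg)
  })
  adult <- .stage("adult_networks", clip_to_estuaries(net$networks, estuaries, grid))
  edges <- .stage("connectivity", optimal_connections(net$networks, grid))
  iso <- .stage("isolation", isolation_metric(net$networks, edges))

  net_summary <- net$networks %>%
    dplyr::select("network_id", "species", "n_members",
                  larval_area_km2 = "area_km2") %>%
    dplyr::left_join(dplyr::select(adult, "network_id",
                                   adult_area_km2 = "area_km2"),
                     by = "network_id") %>%
    dplyr::left_join(iso, by = "network_id")
  readr::write_csv(net_summary, file.path(out_dir, "networks_summary.csv"), na = "")
  readr::write_csv(edges, file.path(out_dir, "network_connections.csv"), na = "")
  write_geojson_polygons(
    dplyr::select(dplyr::left_join(net$networks,
                                   dplyr::select(iso, "network_id", "isolation_m"),
                                   by = "network_id"),
                  "network_id", "species", "n_members", "area_km2",
                  "isolation_m", "polygon"),
    file.path(out_dir, "networks.geojson"))

  substrate <- .stage("substrate", {
    tab <- substrate_counts(records, "by_region")
    tests <- if (nrow(tab) >= 2) {
      kept <- tryCatch(filter_regions(tab), error = function(e) NULL)
      if (!is.null(kept) && nrow(kept) >= 2) {
        dplyr::mutate(chi_square(use_matrix(kept)), test = "by_region",
                      .before = 1)
      } else NULL
    } else NULL
    sp_tab <- substrate_counts(records, "by_species")
    if (nrow(sp_tab) >= 2) {
      tests <- dplyr::bind_rows(tests,
        dplyr::mutate(chi_square(use_matrix(sp_tab)), test = "by_species",
                      .before = 1))
    }
    readr::write_csv(tab, file.path(out_dir, "substrate_counts_region.csv"), na = "")
    readr::write_csv(sp_tab, file.path(out_dir, "substrate_counts_species.csv"), na = "")
    if (!is.null(tests)) {
      readr::write_csv(tests, file.path(out_dir, "substrate_tests.csv"), na = "")
    }
    list(by_region = tab, by_species = sp_tab, tests = tests)
  })

  selection <- if (!is.null(availability)) {
    .stage("selection", {
      purrr::map(rlang::set_names(unique(records$species)), function(sp) {
        counts <- substrate_counts(dplyr::filter(records, .data$species == sp),
                                   "by_species")
        use <- unlist(counts[1, substrate_classes])
        if (sum(use) < 1) return(NULL)
        sel <- selection_analysis(use, availability, alpha = alpha)
        readr::write_csv(sel, file.path(out_dir, sprintf("selection_%s.csv", sp)),
                         na = "")
        sel
      })
    })
  } else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("oysternet")),
    r_version = R.version.string,
    seed = seed,
    parameters = list(cell_size = cell_size, min_records = min_records,
                      alpha = alpha, d_max = cfg$d_max, d_link = cfg$d_link,
                      snap_max = cfg$snap_max, min_members = cfg$min_members,
                      connectivity = cfg$connectivity),
    counts = list(records = nrow(records),
                  rejected = nrow(attr(records, "rejected") %||% tibble::tibble()),
                  networks = nrow(net$networks),
                  unassigned_records = length(net$unassigned))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(summary = summary_tbl, indices = indices, changes = changes,
                 networks = net, adult_networks = adult, connections = edges,
                 isolation = iso, substrate = substrate, selection = selection,
                 manifest = manifest, grid = grid))
}
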