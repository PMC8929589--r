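# Record data model and IO.
#
# A record set is a plain tibble, one row per site-level observation. A site
# is a point at the center of a 20-m stretch of low intertidal shoreline; the
# abundance class encodes whether living oysters were common (>100 at the
# site), rare (1-100), present with unknown abundance, or absent.

#' Controlled vocabularies for oyster records
#'
#' Factor levels used throughout the package: two species (the native Olympia
#' oyster `O_lurida` and the non-native Pacific oyster `M_gigas`), four
#' abundance classes, six substrate classes plus `unknown`, and three record
#' source types.
#'
#' @name vocabularies
#' @export
oyster_species <- c("O_lurida", "M_gigas")

#' @rdname vocabularies
#' @export
abundance_classes <- c("common", "rare", "present_unknown", "absent")

#' @rdname vocabularies
#' @export
substrate_classes <- c("riprap_boulder", "cobble", "gravel_pebble",
                       "sandflat_mudflat", "seawall_dock_piling",
                       "other_anthropogenic")

#' @rdname vocabularies
#' @export
source_types <- c("published", "unpublished", "inaturalist")

#' @rdname vocabularies
#' @export
state_provinces <- c("Canada", "Washington", "Oregon", "NorthernCalifornia",
                     "SouthernCalifornia", "Mexico")

# presence = any class but absent
presence_classes <- c("common", "rare", "present_unknown")

# earliest record the schema admits (first European expedition record)
.year_min <- 1602
# end of the "current" analysis window
.current_window <- c(2000L, 2020L)

# ---- enum normalization -----------------------------------------------------

.norm_token <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[^a-z0-9]+", "_", x)
}

.synonyms <- list(
  species = c(
    o_lurida = "O_lurida", ostrea_lurida = "O_lurida", o_lurida_ = "O_lurida",
    lurida = "O_lurida", olympia = "O_lurida", olympia_oyster = "O_lurida",
    m_gigas = "M_gigas", magallana_gigas = "M_gigas",
    crassostrea_gigas = "M_gigas", c_gigas = "M_gigas", gigas = "M_gigas",
    pacific_oyster = "M_gigas"
  ),
  abundance_class = c(
    common = "common", c = "common", `_100` = "common",
    rare = "rare", r = "rare", `1_100` = "rare",
    present_unknown = "present_unknown", present = "present_unknown",
    present_but_unknown_abundance = "present_unknown",
    present_unknown_abundance = "present_unknown", p = "present_unknown",
    absent = "absent", a = "absent", none = "absent"
  ),
  substrate_class = c(
    riprap_boulder = "riprap_boulder", riprap = "riprap_boulder",
    boulder = "riprap_boulder", riprap_or_boulder = "riprap_boulder",
    cobble = "cobble",
    gravel_pebble = "gravel_pebble", gravel = "gravel_pebble",
    pebble = "gravel_pebble",
    sandflat_mudflat = "sandflat_mudflat", sandflat = "sandflat_mudflat",
    mudflat = "sandflat_mudflat", sand = "sandflat_mudflat",
    mud = "sandflat_mudflat",
    seawall_dock_piling = "seawall_dock_piling", seawall = "seawall_dock_piling",
    dock = "seawall_dock_piling", piling = "seawall_dock_piling",
    other_anthropogenic = "other_anthropogenic", other = "other_anthropogenic",
    other_anthropogenic_structure = "other_anthropogenic",
    unknown = "unknown", na = "unknown"
  ),
  source_type = c(
    published = "published", pub = "published", literature = "published",
    unpublished = "unpublished", unpub = "unpublished",
    inaturalist = "inaturalist", inat = "inaturalist"
  )
)

#' Normalize enum tokens
#'
#' Case-insensitive normalization with a published synonym table: tokens are
#' lowercased, punctuation collapsed to underscores, and matched against
#' synonyms (e.g. `"Riprap/Boulder"` becomes `"riprap_boulder"`,
#' `"Crassostrea gigas"` becomes `"M_gigas"`). Unknown tokens return `NA`.
#'
#' @param x Character vector of raw tokens.
#' @param field One of `"species"`, `"abundance_class"`, `"substrate_class"`,
#'   `"source_type"`.
#' @return Character vector of canonical tokens, `NA` where unrecognized.
#' @export
normalize_enum <- function(x, field) {
  tab <- .synonyms[[match.arg(field, names(.synonyms))]]
  out <- unname(tab[.norm_token(x)])
  out
}

# ---- validation -------------------------------------------------------------

.required_cols <- c("record_id", "species", "x", "y", "year",
                    "abundance_class", "source_type")

# returns list(accepted = tibble, rejected = tibble(row, record_id, reason))
validate_records <- function(raw) {
  missing <- setdiff(.required_cols, names(raw))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  raw <- tibble::as_tibble(raw)
  n <- nrow(raw)
  opt_default <- function(col, default) {
    if (col %in% names(raw)) raw[[col]] else rep(default, n)
  }
  rec <- tibble::tibble(
    record_id = as.character(raw$record_id),
    species = normalize_enum(raw$species, "species"),
    x = as.numeric(raw$x),
    y = as.numeric(raw$y),
    lon = as.numeric(opt_default("lon", NA_real_)),
    lat = as.numeric(opt_default("lat", NA_real_)),
    year = suppressWarnings(as.integer(raw$year)),
    abundance_class = normalize_enum(raw$abundance_class, "abundance_class"),
    substrate_class = {
      raw_sub <- opt_default("substrate_class", NA_character_)
      s <- normalize_enum(raw_sub, "substrate_class")
      # an absent or blank substrate is legitimately unknown; an unrecognized
      # token stays NA and is rejected below
      s[is.na(raw_sub) | trimws(as.character(raw_sub)) == ""] <- "unknown"
      s
    },
    source_type = normalize_enum(raw$source_type, "source_type"),
    estuary_id = as.character(opt_default("estuary_id", NA_character_)),
    sensitive = {
      s <- opt_default("sensitive", FALSE)
      if (is.character(s)) s <- tolower(s) %in% c("true", "t", "1", "yes")
      as.logical(ifelse(is.na(s), FALSE, s))
    }
  )
  current_year <- as.integer(format(Sys.Date(), "%Y"))
  reasons <- character(n)
  add_reason <- function(bad, why) {
    bad <- which(bad)
    reasons[bad] <<- ifelse(reasons[bad] == "", why, paste(reasons[bad], why, sep = "; "))
  }
  add_reason(is.na(rec$record_id) | rec$record_id == "", "missing record_id")
  add_reason(duplicated(rec$record_id), "duplicate record_id")
  add_reason(is.na(rec$species), "unknown species token")
  add_reason(is.na(rec$abundance_class), "unknown abundance token")
  add_reason(is.na(rec$substrate_class), "unknown substrate token")
  add_reason(is.na(rec$source_type), "unknown source token")
  add_reason(!is.finite(rec$x) | !is.finite(rec$y), "non-finite coordinates")
  add_reason(is.na(rec$year) | rec$year < .year_min | rec$year > current_year,
             sprintf("year outside [%d, %d]", .year_min, current_year))
  add_reason(!is.na(rec$lat) & (rec$lat < -90 | rec$lat > 90), "latitude out of range")
  add_reason(!is.na(rec$lon) & (rec$lon < -180 | rec$lon > 180), "longitude out of range")

  ok <- reasons == ""
  list(
    accepted = rec[ok, , drop = FALSE],
    rejected = tibble::tibble(row = which(!ok),
                              record_id = rec$record_id[!ok],
                              reason = reasons[!ok])
  )
}

#' Read oyster occurrence records
#'
#' Reads a record table from CSV or GeoJSON point features, normalizes enum
#' tokens via [normalize_enum()], and validates every row against the record
#' schema (finite planar coordinates, year within 1602 to the current year,
#' known species/abundance/substrate/source tokens, unique ids). Rows that
#' violate the schema are rejected with row-level diagnostics, available as
#' `attr(x, "rejected")`.
#'
#' @param path Input file path.
#' @param format `"csv"` (documented column dictionary: `record_id, species,
#'   x, y, lon, lat, year, abundance_class, substrate_class, source_type,
#'   estuary_id, sensitive`; only the first seven before `substrate_class` are
#'   required) or `"geojson"` point features with the same properties.
#' @return A tibble of accepted records with a `rejected` attribute holding
#'   the diagnostics table.
#' @export
read_records <- function(path, format = c("csv", "geojson")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- switch(format,
    csv = readr::read_csv(path, show_col_types = FALSE),
    geojson = read_geojson_points(path)
  )
  res <- validate_records(raw)
  message(sprintf("read_records: %d accepted, %d rejected",
                  nrow(res$accepted), nrow(res$rejected)))
  structure(res$accepted, rejected = res$rejected)
}

#' Write oyster occurrence records
#'
#' @param records Record tibble.
#' @param path Output path.
#' @param format `"csv"` or `"geojson"`.
#' @param redact If `TRUE`, records flagged `sensitive` are exported with
#'   coordinates blanked (see [redact_sensitive()]); the in-memory object is
#'   untouched.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, format = c("csv", "geojson"),
                          redact = FALSE) {
  format <- match.arg(format)
  out <- if (redact) redact_sensitive(records) else records
  out <- tibble::as_tibble(as.data.frame(out))
  switch(format,
    csv = readr::write_csv(out, path, na = ""),
    geojson = write_geojson_points(out, path)
  )
  invisible(path)
}

#' Blank coordinates of sensitive records
#'
#' Produces an export copy in which records flagged `sensitive` have their
#' planar and geographic coordinates set to `NA`. Analyses keep using the
#' original, un-redacted records.
#'
#' @param records Record tibble.
#' @return Tibble with coordinates nulled on sensitive rows.
#' @export
redact_sensitive <- function(records) {
  dplyr::mutate(records, dplyr::across(
    dplyr::any_of(c("x", "y", "lon", "lat")),
    ~ ifelse(.data$sensitive, NA_real_, .x)
  ))
}

# ---- temporal and geographic classification ---------------------------------

#' Classify record years into analysis periods
#'
#' The temporal contrast is pre-2000 versus the "current" period 2000-2020.
#' Years before 2000 map to `"pre2000"`; 2000-2020 map to `"post2000"`; years
#' after 2020 fall outside the current window and map to `NA` (they are kept
#' in the database but excluded from current-period analyses).
#'
#' @param year Integer vector of calendar years.
#' @return Character vector of `"pre2000"` / `"post2000"` / `NA`.
#' @export
assign_period <- function(year) {
  dplyr::case_when(
    year < .current_window[1] ~ "pre2000",
    year <= .current_window[2] ~ "post2000",
    TRUE ~ NA_character_
  )
}

#' @rdname assign_period
#' @param records Record tibble; gains a `period` column.
#' @export
add_period <- function(records) {
  dplyr::mutate(records, period = assign_period(.data$year))
}

#' Build an estuary polygon table
#'
#' @param estuary_id Character ids.
#' @param polygon List of polygons (each a list of rings or a single ring
#'   matrix).
#' @param region State/province label per estuary (one of
#'   [state_provinces]).
#' @return Tibble with `estuary_id`, `region`, `polygon`, `area_km2`,
#'   `centroid_x`, `centroid_y`.
#' @export
estuary_set <- function(estuary_id, polygon, region) {
  stopifnot(length(estuary_id) == length(polygon),
            !anyDuplicated(estuary_id),
            all(region %in% state_provinces))
  polygon <- purrr::map(polygon, as_poly)
  cent <- purrr::map(polygon, poly_centroid)
  tibble::tibble(
    estuary_id = as.character(estuary_id),
    region = region,
    polygon = polygon,
    area_km2 = purrr::map_dbl(polygon, poly_area) / 1e6,
    centroid_x = purrr::map_dbl(cent, 1),
    centroid_y = purrr::map_dbl(cent, 2)
  )
}

#' Map state/province regions to broad regions
#'
#' North = Canada + Washington; Central = Oregon + Northern California;
#' South = Southern California + Mexico.
#'
#' @param region Character vector of state/province labels.
#' @return Character vector of `"North"` / `"Central"` / `"South"`.
#' @export
region_broad <- function(region) {
  dplyr::case_when(
    region %in% c("Canada", "Washington") ~ "North",
    region %in% c("Oregon", "NorthernCalifornia") ~ "Central",
    region %in% c("SouthernCalifornia", "Mexico") ~ "South",
    TRUE ~ NA_character_
  )
}

#' Split Californian records at Point Conception
#'
#' California is divided into northern and southern portions at Point
#' Conception, a widely recognized biogeographic boundary. For records whose
#' region is given as plain `"California"`, the latitude decides the side.
#'
#' @param records Record tibble with `region` and `lat` columns.
#' @param boundary_lat Boundary latitude in degrees north (default the Point
#'   Conception landmark, 34.4486).
#' @return Records with `region` rewritten to `NorthernCalifornia` /
#'   `SouthernCalifornia` where it was `"California"`.
#' @export
split_california <- function(records, boundary_lat = 34.4486) {
  dplyr::mutate(records, region = dplyr::case_when(
    .data$region != "California" ~ .data$region,
    .data$lat >= boundary_lat ~ "NorthernCalifornia",
    .data$lat < boundary_lat ~ "SouthernCalifornia",
    TRUE ~ NA_character_
  ))
}

#' Assign records to estuaries by spatial join
#'
#' A record inside an estuary polygon gets that `estuary_id`. A record
#' outside all polygons but within `max_assign_m` of one gets the nearest.
#' Anything farther keeps `estuary_id = NA` (an open-coast record). Records
#' contained by more than one polygon raise an ambiguity warning (first match
#' kept). A `region` column is joined from the estuary table.
#'
#' @param records Record tibble with planar `x`, `y`.
#' @param estuaries Estuary tibble from [estuary_set()].
#' @param max_assign_m Nearest-polygon tolerance in meters (default 0: strict
#'   containment only).
#' @return Records with `estuary_id` and `region` filled in.
#' @export
assign_estuary <- function(records, estuaries, max_assign_m = 0) {
  n <- nrow(records)
  est_id <- rep(NA_character_, n)
  ambiguous <- character(0)
  for (j in seq_len(nrow(estuaries))) {
    inside <- poly_contains(estuaries$polygon[[j]], records$x, records$y)
    newly <- inside & is.na(est_id)
    clash <- inside & !is.na(est_id)
    if (any(clash)) ambiguous <- c(ambiguous, records$record_id[clash])
    est_id[newly] <- estuaries$estuary_id[j]
  }
  if (length(ambiguous) > 0) {
    warning("records inside overlapping estuary polygons (first match kept): ",
            paste(unique(ambiguous), collapse = ", "))
  }
  if (max_assign_m > 0 && any(is.na(est_id))) {
    for (i in which(is.na(est_id))) {
      d <- vapply(estuaries$polygon,
                  function(p) poly_distance(p, records$x[i], records$y[i]),
                  numeric(1))
      if (min(d) <= max_assign_m) est_id[i] <- estuaries$estuary_id[which.min(d)]
    }
  }
  records$estuary_id <- est_id
  dplyr::left_join(
    dplyr::select(records, -dplyr::any_of("region")),
    dplyr::select(estuaries, "estuary_id", "region"),
    by = "estuary_id"
  )
}

#' Summarize the record database
#'
#' Counts records by species, presence/absence, source type, and region
#' (presence = common, rare, or present with unknown abundance), the shape of
#' the database summary table.
#'
#' @param records Record tibble with a `region` column.
#' @return Tibble with columns `species`, `region`, `source_type`,
#'   `presence`, `absence`, `total`, including per-species totals under
#'   `region = "Total"`.
#' @export
summarize_database <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(species = character(), region = character(),
                          source_type = character(), presence = integer(),
                          absence = integer(), total = integer()))
  }
  base <- records %>%
    dplyr::mutate(status = ifelse(.data$abundance_class %in% presence_classes,
                                  "presence", "absence")) %>%
    dplyr::count(.data$species, .data$region, .data$source_type, .data$status) %>%
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L)
  for (col in c("presence", "absence")) {
    if (!col %in% names(base)) base[[col]] <- 0L
  }
  base <- dplyr::mutate(base, total = .data$presence + .data$absence)
  totals <- base %>%
    dplyr::group_by(.data$species) %>%
    dplyr::summarise(region = "Total", source_type = "all",
                     presence = sum(.data$presence), absence = sum(.data$absence),
                     total = sum(.data$total), .groups = "drop")
  dplyr::bind_rows(base, totals)
}
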