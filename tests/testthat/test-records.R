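test_that("CSV round trip is the identity on accepted records", {
  recs <- mix_records(common = 2, rare = 1, present = 1, absent = 1,
                      substrate = c("riprap_boulder", "cobble", "gravel_pebble",
                                    "sandflat_mudflat", "unknown"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(dplyr::select(recs, -region), path)
  back <- suppressMessages(read_records(path))
  expect_equal(nrow(back), 5)
  expect_equal(nrow(attr(back, "rejected")), 0)
  attr(back, "rejected") <- NULL
  expect_equal(as.data.frame(back),
               as.data.frame(dplyr::select(recs, -region)))
})

test_that("GeoJSON point round trip preserves records", {
  recs <- dplyr::select(mix_records(common = 3, absent = 2), -region)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_records(recs, path, format = "geojson")
  back <- suppressMessages(read_records(path, format = "geojson"))
  expect_equal(as.data.frame(back)[order(back$record_id), names(recs)],
               as.data.frame(recs))
})

test_that("enum tokens are normalized case-insensitively with synonyms", {
  expect_equal(normalize_enum("Common", "abundance_class"), "common")
  expect_equal(normalize_enum("Present", "abundance_class"), "present_unknown")
  expect_equal(normalize_enum("Crassostrea gigas", "species"), "M_gigas")
  expect_equal(normalize_enum("Riprap/Boulder", "substrate_class"), "riprap_boulder")
  expect_equal(normalize_enum("iNat", "source_type"), "inaturalist")
  expect_true(is.na(normalize_enum("oyster?", "species")))
})

test_that("invalid rows are rejected with row-level diagnostics", {
  recs <- make_records(4)
  recs$year[2] <- 1500L          # before the earliest admissible record
  recs$x[3] <- NA_real_
  recs$record_id[4] <- recs$record_id[1]  # duplicate id
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(recs, -region), path)
  got <- suppressMessages(read_records(path))
  expect_equal(nrow(got), 1)
  rej <- attr(got, "rejected")
  expect_setequal(rej$row, c(2, 3, 4))
  expect_match(rej$reason[rej$row == 2], "year")
  expect_match(rej$reason[rej$row == 3], "coordinates")
  expect_match(rej$reason[rej$row == 4], "duplicate")
})

test_that("missing required columns raise an error", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(record_id = "a", species = "O_lurida"), path)
  expect_error(read_records(path), "missing required column")
})

test_that("period assignment is total and monotone on valid years", {
  expect_equal(assign_period(c(1999L, 2000L, 2020L)),
               c("pre2000", "post2000", "post2000"))
  expect_true(is.na(assign_period(2021L)))
  years <- 1900:2020
  per <- factor(assign_period(years), levels = c("pre2000", "post2000"))
  expect_false(is.unsorted(as.integer(per)))
})

test_that("sensitive coordinates are redacted only in the export copy", {
  recs <- make_records(3, sensitive = c(TRUE, FALSE, TRUE))
  red <- redact_sensitive(recs)
  expect_true(all(is.na(red$x[c(1, 3)])))
  expect_equal(red$x[2], recs$x[2])
  expect_false(any(is.na(recs$x)))  # analysis copy untouched
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(dplyr::select(recs, -region), path, redact = TRUE)
  exported <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(sum(is.na(exported$x)), 2)
})

test_that("estuary assignment handles containment, tolerance, and open coast", {
  est <- estuary_set(c("E1", "E2"),
                     list(rect_ring(0, 0, 1000, 1000),
                          rect_ring(5000, 0, 6000, 1000)),
                     region = c("Washington", "Oregon"))
  recs <- make_records(3, x = c(500, 1050, 60000), y = c(500, 500, 500))
  got <- assign_estuary(recs, est, max_assign_m = 1000)
  expect_equal(got$estuary_id, c("E1", "E1", NA))
  expect_equal(got$region, c("Washington", "Washington", NA))
  # nearest-polygon tie goes to the true nearest, by brute force over all
  mid <- make_records(1, x = 2900, y = 500)  # 1900 m from E1, 2100 m from E2
  got2 <- assign_estuary(mid, est, max_assign_m = 2000)
  expect_equal(got2$estuary_id, "E1")
  # overlapping polygons report ambiguity
  ovl <- estuary_set(c("A", "B"),
                     list(rect_ring(0, 0, 1000, 1000), rect_ring(0, 0, 1000, 1000)),
                     region = c("Washington", "Washington"))
  expect_warning(assign_estuary(make_records(1, x = 500, y = 500), ovl),
                 "overlapping")
})

test_that("Point Conception split is driven by the configurable latitude", {
  recs <- make_records(2, region = "California")
  recs$lat <- c(36, 33)
  got <- split_california(recs)
  expect_equal(got$region, c("NorthernCalifornia", "SouthernCalifornia"))
  got2 <- split_california(recs, boundary_lat = 32)
  expect_equal(got2$region, rep("NorthernCalifornia", 2))
})

test_that("broad regions map states and provinces as North/Central/South", {
  expect_equal(region_broad(state_provinces),
               c("North", "North", "Central", "Central", "South", "South"))
})

test_that("database summary counts match a planted composition", {
  recs <- dplyr::bind_rows(
    mix_records(common = 3, absent = 2, region = "Washington", id_prefix = "A"),
    mix_records(rare = 4, present = 1, absent = 3, region = "Oregon",
                species = "M_gigas", id_prefix = "B")
  )
  got <- summarize_database(recs)
  ol <- dplyr::filter(got, species == "O_lurida", region == "Washington")
  expect_equal(ol$presence, 3)
  expect_equal(ol$absence, 2)
  mg_tot <- dplyr::filter(got, species == "M_gigas", region == "Total")
  expect_equal(mg_tot$presence, 5)
  expect_equal(mg_tot$absence, 3)
  # presence + absence equals total in every cell
  expect_true(all(got$presence + got$absence == got$total))
  expect_equal(nrow(summarize_database(make_records(0)[0, ])), 0)
})
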