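test_that("rasterization marks cells water by polygon coverage of centers", {
  g <- open_grid(1000, 500, 100)
  expect_true(all(g$water))
  expect_equal(dim(g$water), c(5, 10))
  island <- list(rect_ring(200, 100, 500, 300))
  g2 <- rasterize_coast(list(island), c(0, 0, 1000, 500), 100)
  # cells whose centers fall in [200,500]x[100,300]: cols 3-5, rows 2-3
  expect_equal(sum(!g2$water), 6)
  expect_false(any(g2$water[2:3, 3:5]))
  expect_error(rasterize_coast(list(list(rect_ring(-10, -10, 1100, 600))),
                               c(0, 0, 1000, 500), 100), "no water")
})

test_that("along-water distances match straight-line and diagonal metrics", {
  g <- open_grid(2000, 1000, 10)
  src <- matrix(c(5, 505), 1, 2)  # row 51, col 1
  d <- water_distance(g, src)
  expect_equal(d[51, 101], 1000)          # 100 columns east
  expect_equal(d[54, 4], 30 * sqrt(2))    # 3-cell pure diagonal
  expect_equal(d[52, 3], 10 * sqrt(5))    # knight move at 16-connectivity
  expect_true(all(!is.finite(water_distance(g, src, d_max = 500)[, 101])))
})

test_that("barrier detours match an independent igraph shortest-path oracle", {
  # U-shaped barrier forcing a detour
  land <- list(list(rect_ring(400, 0, 420, 800)))
  g <- rasterize_coast(land, c(0, 0, 1000, 1000), 20)
  from <- c(25, 10)  # west of the wall
  to <- c(25, 30)    # east of the wall
  d <- water_distance(g, matrix(c((from[2] - 0.5) * 20, (from[1] - 0.5) * 20),
                                1, 2))
  got <- d[to[1], to[2]]
  want <- oracle_grid_distance(g$water, 20, 16, from, to)
  expect_equal(got, want, tolerance = 1e-9)
  expect_gt(got, sqrt(sum((c(400, 0))^2)))  # longer than the straight line
})

test_that("water distance dominates Euclidean and stays within the metric bound", {
  withr::local_seed(31)
  g <- open_grid(3000, 3000, 10)
  src_rc <- c(150, 150)
  d <- water_distance(g, matrix(c(1495, 1495), 1, 2))
  for (i in 1:100) {
    rc <- c(sample(300, 1), sample(300, 1))
    sep <- sqrt(sum((rc - src_rc)^2))
    if (sep < 20) next
    eucl <- 10 * sep
    expect_gte(d[rc[1], rc[2]] + 1e-9, eucl - 10 * sqrt(2))
    expect_lte(d[rc[1], rc[2]], 1.03 * eucl)
  }
})

test_that("snapping moves inland records to water and excludes far ones", {
  land <- list(list(rect_ring(0, 0, 2000, 500)))
  g <- rasterize_coast(land, c(0, 0, 2000, 1000), 50)
  recs <- make_records(3, x = c(1000, 1000, 1000), y = c(700, 300, 5))
  # on water; 300 m inland (snaps); ~520 m inland with snap_max 400 (excluded)
  snapped <- suppressWarnings(snap_to_water(recs, g, snap_max = 400))
  expect_equal(nrow(snapped), 2)
  expect_equal(snapped$y[1], 700)  # untouched
  rc <- oysternet:::grid_rowcol(g, snapped$x[2], snapped$y[2])
  expect_true(g$water[rc])
  expect_equal(attr(snapped, "excluded")$record_id, "T003")
})

test_that("linkage is transitive through chains and respects min_members", {
  g <- open_grid(120e3, 10e3, 500)
  # A-B 25 km, B-C 25 km, A-C 50 km: one network; D isolated at > 30 km
  recs <- make_records(4, x = c(10e3, 35e3, 60e3, 115e3), y = 5e3,
                       year = 2010)
  net <- suppressMessages(build_larval_networks(recs, g, network_config()))
  expect_equal(nrow(net$networks), 1)
  expect_equal(net$networks$n_members, 3)
  expect_setequal(net$membership$record_id, c("T001", "T002", "T003"))
  expect_equal(net$unassigned, "T004")
  # min_members = 3 removes a pair-only component
  pair <- make_records(2, x = c(10e3, 20e3), y = 5e3, year = 2010)
  net2 <- build_larval_networks(pair, g, network_config())
  expect_equal(nrow(net2$networks), 1)
  net3 <- suppressMessages(
    build_larval_networks(pair, g, network_config(min_members = 3)))
  expect_equal(nrow(net3$networks), 0)
  # absence and pre-2000 records never enter
  stale <- dplyr::bind_rows(
    make_records(2, x = c(10e3, 20e3), y = 5e3, year = 1990, id_prefix = "P"),
    make_records(2, x = c(10e3, 20e3), y = 5e3, abundance = "absent",
                 id_prefix = "Q"))
  expect_error(build_larval_networks(stale, g, network_config()),
               "no eligible")
})

test_that("adding a record never splits a network; removal never merges", {
  g <- open_grid(100e3, 10e3, 500)
  base <- make_records(3, x = c(10e3, 35e3, 60e3), y = 5e3, year = 2010)
  net_base <- build_larval_networks(base, g, network_config())
  plus <- dplyr::bind_rows(base, make_records(1, x = 80e3, y = 5e3,
                                              year = 2010, id_prefix = "X"))
  net_plus <- build_larval_networks(plus, g, network_config())
  # the original members still share one network
  m <- dplyr::filter(net_plus$membership, record_id %in% base$record_id)
  expect_equal(dplyr::n_distinct(m$network_id), 1)
  expect_gte(nrow(net_plus$membership), nrow(net_base$membership))
})

test_that("network polygons cover members and adult clip matches analytic areas", {
  g <- open_grid(100e3, 20e3, 500)
  recs <- make_records(2, x = c(20e3, 30e3), y = 10e3, year = 2010)
  net <- build_larval_networks(recs, g, network_config())
  expect_equal(nrow(net$networks), 1)
  expect_true(all(poly_contains(net$networks$polygon[[1]], recs$x, recs$y)))
  expect_gt(net$networks$area_km2, 0)
  # clip to a rectangle: adult area = masked cells inside the rectangle
  est <- estuary_set("E1", list(rect_ring(15e3, 5e3, 25e3, 15e3)), "Washington")
  adult <- clip_to_estuaries(net$networks, est, g)
  expect_equal(adult$area_km2, 10 * 10)  # estuary fully inside the 30-km zone
  expect_lte(adult$area_km2, adult$larval_area_km2)
  # an estuary beyond the 30-km reachable zone intersects nothing
  far <- estuary_set("E2", list(rect_ring(90e3, 5e3, 95e3, 15e3)), "Oregon")
  none <- clip_to_estuaries(net$networks, far, g)
  expect_equal(none$area_km2, 0)
})

test_that("optimal connections and isolation follow the north/south rule", {
  g <- open_grid(10e3, 200e3, 500)
  # three single-cluster networks stacked north to south
  recs <- make_records(6, x = 5e3,
                       y = c(190e3, 189e3, 110e3, 109e3, 10e3, 9e3),
                       year = 2010)
  net <- build_larval_networks(recs, g, network_config())
  expect_equal(nrow(net$networks), 3)
  expect_equal(net$networks$network_id, c("O-1", "O-2", "O-3"))
  # north to south ordering by centroid northing
  expect_true(all(diff(net$networks$centroid_y) < 0))
  edges <- optimal_connections(net$networks, g)
  expect_equal(nrow(edges), 3)
  expect_true(all(edges$distance_m >= 0))
  iso <- isolation_metric(net$networks, edges)
  d12 <- edges$distance_m[edges$network_a == "O-1" & edges$network_b == "O-2"]
  d23 <- edges$distance_m[edges$network_a == "O-2" & edges$network_b == "O-3"]
  # middle network averages its two flank distances; ends use the single side
  expect_equal(iso$isolation_m[iso$network_id == "O-2"], mean(c(d12, d23)))
  expect_equal(iso$isolation_m[iso$network_id == "O-1"], d12)
  expect_equal(iso$isolation_m[iso$network_id == "O-3"], d23)
  expect_true(is.na(iso$dist_north_m[iso$network_id == "O-1"]))
})

test_that("touching networks are at connection distance zero", {
  g <- open_grid(80e3, 10e3, 500)
  recs <- make_records(4, x = c(5e3, 6e3, 45e3, 46e3), y = 5e3, year = 2010)
  cfg <- network_config(d_link = 30000, d_max = 30000)
  net <- build_larval_networks(recs, g, cfg)
  expect_equal(nrow(net$networks), 2)
  edges <- optimal_connections(net$networks, g)
  expect_equal(edges$distance_m, 0)  # 30-km zones overlap between the pairs
})
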