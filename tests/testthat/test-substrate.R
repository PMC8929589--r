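test_that("substrate counts tally presence records per class and log exclusions", {
  recs <- dplyr::bind_rows(
    make_records(10, substrate = "riprap_boulder", region = "SouthernCalifornia"),
    make_records(3, substrate = "unknown", region = "SouthernCalifornia",
                 id_prefix = "U"),
    make_records(2, substrate = "cobble", abundance = "absent",
                 region = "SouthernCalifornia", id_prefix = "A")
  )
  tab <- substrate_counts(recs, "by_region")
  expect_equal(nrow(tab), 1)
  expect_equal(unlist(tab[1, substrate_classes], use.names = FALSE),
               c(10, 0, 0, 0, 0, 0))
  expect_equal(attr(tab, "n_excluded"), 3)  # unknown substrate, presence only
  # pre-2000 records don't enter the current-period table
  old <- make_records(5, year = 1980, substrate = "cobble",
                      region = "SouthernCalifornia", id_prefix = "O")
  tab2 <- substrate_counts(dplyr::bind_rows(recs, old), "by_region")
  expect_equal(tab2$cobble, 0)
})

test_that("region filter removes groups with any sparse category at the boundary", {
  tab <- tibble::tibble(group = c("A", "B", "C"))
  m <- rbind(c(5, 6, 7, 8, 9, 10), c(5, 5, 5, 5, 5, 5), c(10, 10, 10, 10, 4, 10))
  for (i in seq_along(substrate_classes)) tab[[substrate_classes[i]]] <- m[, i]
  kept <- suppressMessages(filter_regions(tab))
  expect_setequal(kept$group, c("A", "B"))  # min cell 5 retained, 4 removed
  # brute-force: removal list equals rows whose min is below threshold
  expect_setequal(setdiff(tab$group, kept$group),
                  tab$group[apply(m, 1, min) < 5])
  expect_error(filter_regions(tab, min_count = 11), "all groups removed")
})

test_that("selection index and CI calls follow the availability rule", {
  use <- c(riprap_boulder = 50, cobble = 0, gravel_pebble = 10,
           sandflat_mudflat = 30, seawall_dock_piling = 8,
           other_anthropogenic = 2)
  p <- availability_profile(c(riprap_boulder = 0.2, cobble = 0.1,
                              gravel_pebble = 0.2, sandflat_mudflat = 0.2,
                              seawall_dock_piling = 0.2,
                              other_anthropogenic = 0.1))
  sel <- selection_analysis(use, p)
  expect_equal(sel$u_i, unname(use) / 100)
  expect_equal(sel$w_i, ifelse(sel$u_i == 0, 0, sel$u_i / sel$p_i))
  expect_equal(sel$w_i[sel$habitat == "cobble"], 0)  # zero use, zero index
  expect_equal(sum(sel$w_i * sel$p_i), 1)
  expect_true(all(sel$ci_low <= sel$u_i & sel$u_i <= sel$ci_high))
  expect_equal(sel$call, dplyr::case_when(
    sel$p_i < sel$ci_low ~ "preference",
    sel$p_i > sel$ci_high ~ "avoidance",
    TRUE ~ "proportional"))
  # equal use and availability is proportional with w = 1
  even_use <- rlang::set_names(rep(10, 6), substrate_classes)
  even_p <- availability_profile(rlang::set_names(rep(1 / 6, 6), substrate_classes))
  sel2 <- selection_analysis(even_use, even_p)
  expect_equal(sel2$w_i, rep(1, 6))
  expect_true(all(sel2$call == "proportional"))
  expect_equal(sum(sel2$w_i * sel2$p_i), 1)
})

test_that("use on zero-availability habitat is flagged, not infinite", {
  use <- rlang::set_names(c(10, 5, 0, 0, 0, 1), substrate_classes)
  p <- availability_profile(rlang::set_names(c(0.5, 0.3, 0.1, 0.05, 0.05, 0),
                                             substrate_classes))
  expect_warning(sel <- selection_analysis(use, p), "zero availability")
  expect_true(is.na(sel$w_i[sel$habitat == "other_anthropogenic"]))
})

test_that("widening alpha can only move calls toward preference/avoidance", {
  withr::local_seed(21)
  for (i in 1:25) {
    counts <- rlang::set_names(rmultinom(1, 60, runif(6) + 0.05)[, 1],
                               substrate_classes)
    p <- runif(6) + 0.05
    p <- availability_profile(rlang::set_names(p / sum(p), substrate_classes))
    narrow <- selection_analysis(counts, p, alpha = 0.01)
    wide <- selection_analysis(counts, p, alpha = 0.10)
    # wider alpha means narrower intervals: proportional calls can flip to
    # preference/avoidance but never the reverse
    flipped_back <- narrow$call != "proportional" & wide$call == "proportional"
    expect_false(any(flipped_back))
  }
})

test_that("wilson intervals are an available alternative", {
  use <- rlang::set_names(c(12, 8, 5, 20, 10, 5), substrate_classes)
  p <- availability_profile(rlang::set_names(rep(1 / 6, 6), substrate_classes))
  b <- selection_analysis(use, p, ci_method = "bonferroni")
  w <- selection_analysis(use, p, ci_method = "wilson")
  expect_false(isTRUE(all.equal(b$ci_low, w$ci_low)))
  expect_true(all(w$ci_low >= 0 & w$ci_high <= 1))
})
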