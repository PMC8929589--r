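test_that("signed-rank test matches enumeration and wilcox.test on small samples", {
  withr::local_seed(42)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    d <- round(rnorm(n), 2)
    for (alt in c("two.sided", "less", "greater")) {
      got <- wilcoxon_signed_rank(d, alternative = alt)
      expect_equal(got$p_value, oracle_wilcoxon_p(d, alt), tolerance = 1e-12)
    }
    if (!any(duplicated(abs(d))) && all(d != 0)) {
      expect_equal(wilcoxon_signed_rank(d)$p_value,
                   stats::wilcox.test(d, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("signed-rank exact null handles ties and drops zeros", {
  d <- c(-0.2, -0.1, -0.4, 0.1, -0.3, -0.25)
  got <- wilcoxon_signed_rank(d)
  expect_equal(got$p_value, oracle_wilcoxon_p(d), tolerance = 1e-12)
  with_zeros <- wilcoxon_signed_rank(c(d, 0, 0))
  expect_equal(with_zeros$n, 6L)
  expect_equal(with_zeros$p_value, got$p_value)
  tied <- c(0.3, 0.3, -0.3, 0.5, 0.5, -0.1, 0.2, 0.2)
  expect_equal(wilcoxon_signed_rank(tied)$p_value, oracle_wilcoxon_p(tied),
               tolerance = 1e-12)
})

test_that("signed-rank normal approximation tracks wilcox.test for larger n", {
  withr::local_seed(7)
  d <- rnorm(40)
  got <- wilcoxon_signed_rank(d)
  ref <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_match(got$method, "normal")
})

test_that("kendall tau-b matches pair-counting and permutation oracles", {
  withr::local_seed(99)
  for (i in 1:20) {
    n <- sample(4:7, 1)
    x <- sample(1:4, n, replace = TRUE)  # ties likely
    y <- sample(1:4, n, replace = TRUE)
    if (var(x) == 0 || var(y) == 0) next
    got <- kendall_tau(x, y)
    expect_equal(got$tau, oracle_tau(x, y), tolerance = 1e-12)
    expect_equal(got$p_value, oracle_kendall_p(x, y), tolerance = 1e-12)
  }
  expect_equal(kendall_tau(1:5, 1:5)$tau, 1)
  expect_equal(kendall_tau(1:5, 5:1)$tau, -1)
})

test_that("kendall agrees with cor.test and flags degenerate input", {
  withr::local_seed(13)
  x <- rnorm(30); y <- x + rnorm(30)
  got <- kendall_tau(x, y)
  ref <- stats::cor.test(x, y, method = "kendall", exact = FALSE,
                         continuity = FALSE)
  expect_equal(got$tau, unname(ref$estimate), tolerance = 1e-10)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  flat <- kendall_tau(rep(1, 5), 1:5)
  expect_true(is.na(flat$tau))
  expect_match(flat$method, "degenerate")
})

test_that("kruskal-wallis reproduces the rank formula and degenerate case", {
  got <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # H = 12/(N(N+1)) * sum(R_j^2/n_j) - 3(N+1), ranks 1..6
  H <- 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7
  expect_equal(got$statistic, H, tolerance = 1e-12)
  same <- kruskal_wallis(rep(c(2, 2, 2), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("chi-square equals the direct O/E formula", {
  tab <- matrix(c(10, 20, 20, 10), 2, 2, byrow = TRUE)
  got <- chi_square(tab)
  expect_equal(got$statistic, 100 / 15, tolerance = 1e-12)
  expect_equal(got$df, 1)
  withr::local_seed(5)
  rnd <- matrix(rpois(18, 20) + 1, 3, 6)
  expect_equal(chi_square(rnd)$statistic, oracle_chi2(rnd), tolerance = 1e-10)
  # invariance under row and column permutation
  expect_equal(chi_square(rnd[c(2, 3, 1), c(3, 1, 2, 6, 5, 4)])$statistic,
               chi_square(rnd)$statistic, tolerance = 1e-12)
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2, 2)), "margin")
})

test_that("fisher exact matches hypergeometric enumeration and is reproducible", {
  got <- fisher_exact(matrix(c(3, 1, 1, 3), 2, 2, byrow = TRUE))
  # enumerate all 2x2 tables with margins (4,4),(4,4)
  probs <- dhyper(0:4, 4, 4, 4)
  p_obs <- dhyper(3, 4, 4, 4)
  expect_equal(got$p_value, sum(probs[probs <= p_obs + 1e-12]), tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2, 2))$p_value, 1)
  big <- matrix(c(120, 80, 60, 90, 40, 30, 100, 70, 50, 80, 45, 25), 2, 6,
                byrow = TRUE)
  mc1 <- fisher_exact(big, mc_reps = 2e4, seed = 9)
  mc2 <- fisher_exact(big, mc_reps = 2e4, seed = 9)
  expect_equal(mc1$p_value, mc2$p_value)
  expect_match(mc1$method, "monte_carlo")
  expect_false(is.na(mc1$mc_se))
})

test_that("paired change joins estuaries, filters, and reports percentages", {
  mk <- function(values, n = 5) tibble::tibble(
    estuary_id = sprintf("E%d", seq_along(values)), value = values,
    n_records = n)
  pre <- mk(c(0.8, 0.7, 0.9, 0.5, 0.85, 0.6))
  post <- mk(c(0.6, 0.6, 0.5, 0.6, 0.55, 0.35))
  ch <- paired_change(pre, post)
  expect_s3_class(ch, "oyster_change")
  expect_equal(ch$n_replicates, 6)
  expect_equal(ch$p_value,
               oracle_wilcoxon_p(post$value - pre$value), tolerance = 1e-12)
  expect_equal(ch$pct_declined, 83)
  expect_equal(ch$pct_increased, 17)
  g <- glance(ch)
  expect_equal(g$n_replicates, 6)
  expect_equal(nrow(tidy(ch)), 6)
  # identical vectors: everything unchanged
  same <- paired_change(pre, pre)
  expect_equal(same$pct_unchanged, 100)
  # replicate filter: low-n estuaries drop out
  pre$n_records[1] <- 2
  expect_equal(paired_change(pre, post)$n_replicates, 5)
  # single pair leaves the statistic undefined but keeps percentages
  single <- paired_change(mk(0.8), mk(0.2))
  expect_true(is.na(single$wilcoxon_statistic))
  expect_equal(single$pct_declined, 100)
})

test_that("species comparison is a paired test on the species difference", {
  a <- tibble::tibble(estuary_id = sprintf("E%d", 1:5),
                      value = c(0.9, 0.8, 0.7, 0.95, 0.85), n_records = 4,
                      species = "O_lurida")
  b <- dplyr::mutate(a, value = value - c(0.2, 0.1, 0.15, 0.3, 0.05),
                     species = "M_gigas")
  cmp <- species_paired_comparison(a, b)
  expect_equal(cmp$n_replicates, 5)
  expect_equal(cmp$p_value, oracle_wilcoxon_p(a$value - b$value),
               tolerance = 1e-12)
  expect_equal(cmp$pct_increased, 100)  # a > b everywhere
  expect_equal(species_paired_comparison(a, a)$pct_unchanged, 100)
})
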