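# Nonparametric tests used by the index analyses.
#
# The index data are saturated with ties and exact zeros (many estuaries sit
# at index 0 or 1), so the Wilcoxon signed-rank test here computes an exact
# null even with tied mid-ranks, via a generating-function convolution over
# the rank multiset, and Kendall's correlation is the tie-adjusted tau-b.

#' Wilcoxon signed-rank test
#'
#' Paired signed-rank test on `x - y` (or on `x` directly when `y` is
#' omitted). Zero differences are dropped before ranking (Wilcoxon's original
#' convention); absolute differences receive mid-ranks. For `n <= exact_max`
#' remaining differences the null distribution of the positive-rank sum is
#' computed exactly by convolution (valid under ties); otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric vectors (paired when both given).
#' @param alternative `"two.sided"`, `"less"`, or `"greater"` (on the median
#'   of `x - y`).
#' @param exact_max Largest n for the exact null (default 25).
#' @return One-row tibble: `statistic` (positive-rank sum V), `n` (non-zero
#'   pairs), `p_value`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("two.sided", "less", "greater"),
                                 exact_max = 25) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n < 1) {
    return(tibble::tibble(statistic = NA_real_, n = 0L, p_value = NA_real_,
                          method = "wilcoxon_signed_rank"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact null: V = sum of a random subset of the rank multiset; doubling
    # mid-ranks makes them integers for the convolution
    s <- as.integer(round(2 * r))
    tot <- sum(s)
    prob <- c(1, numeric(tot))
    for (si in s) {
      shifted <- c(numeric(si), prob[seq_len(tot + 1 - si)])
      prob <- (prob + shifted) / 2
    }
    v2 <- round(2 * v)
    support <- 0:tot
    p_le <- sum(prob[support <= v2 + 1e-9])
    p_ge <- sum(prob[support >= v2 - 1e-9])
    p <- switch(alternative,
      less = p_le,
      greater = p_ge,
      two.sided = {
        mu <- tot / 2
        sum(prob[abs(support - mu) >= abs(v2 - mu) - 1e-9])
      }
    )
    method <- "wilcoxon_signed_rank (exact)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- 0.5
    z <- switch(alternative,
      less = (v - mu + cc) / sqrt(sigma2),
      greater = (v - mu - cc) / sqrt(sigma2),
      two.sided = (v - mu - sign(v - mu) * cc) / sqrt(sigma2)
    )
    p <- switch(alternative,
      less = stats::pnorm(z),
      greater = stats::pnorm(z, lower.tail = FALSE),
      two.sided = 2 * stats::pnorm(-abs(z))
    )
    p <- min(1, p)
    method <- "wilcoxon_signed_rank (normal approx.)"
  }
  tibble::tibble(statistic = v, n = n, p_value = p, method = method)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-adjusted Kendall correlation by direct concordant/discordant pair
#' counting. The p-value uses exact permutation enumeration of one margin for
#' `n <= exact_max` and the tie-corrected normal approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param alternative Sidedness of the test.
#' @param exact_max Largest n for exact permutation p (default 8).
#' @return One-row tibble: `tau`, `n`, `p_value`, `method`. `tau` is `NA`
#'   (flagged in `method`) when either vector has zero variance.
#' @export
kendall_tau <- function(x, y, alternative = c("two.sided", "less", "greater"),
                        exact_max = 8) {
  alternative <- match.arg(alternative)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("kendall_tau needs at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(tibble::tibble(tau = NA_real_, n = n, p_value = NA_real_,
                          method = "kendall_tau (degenerate: zero variance)"))
  }
  stat <- .kendall_stat(x, y)
  if (n <= exact_max) {
    perms <- .permutations(n)
    tau_obs <- abs(stat$tau)
    taus <- apply(perms, 1, function(idx) .kendall_stat(x, y[idx])$tau)
    p <- switch(alternative,
      two.sided = mean(abs(taus) >= tau_obs - 1e-12),
      greater = mean(taus >= stat$tau - 1e-12),
      less = mean(taus <= stat$tau + 1e-12)
    )
    method <- "kendall_tau_b (exact permutation)"
  } else {
    # tie-corrected variance of S
    tx <- table(x); ty <- table(y)
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    sigma <- sqrt((v0 - vt - vu) / 18 + v1 + v2)
    z <- stat$S / sigma
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z)
    )
    p <- min(1, p)
    method <- "kendall_tau_b (normal approx.)"
  }
  tibble::tibble(tau = stat$tau, n = n, p_value = p, method = method)
}

.kendall_stat <- function(x, y) {
  n <- length(x)
  S <- 0; n1 <- 0; n2 <- 0
  for (i in seq_len(n - 1)) {
    dx <- x[(i + 1):n] - x[i]
    dy <- y[(i + 1):n] - y[i]
    S <- S + sum(sign(dx) * sign(dy))
    n1 <- n1 + sum(dx != 0)
    n2 <- n2 + sum(dy != 0)
  }
  list(S = S, tau = S / sqrt(n1 * n2))
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic against a chi-square reference, for comparing an
#' index across regions (delegates to [stats::kruskal.test()]).
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 non-empty groups")
  if (length(unique(values)) == 1) {
    # fully tied data: the tie correction degenerates, but H is 0 by definition
    return(tibble::tibble(statistic = 0,
                          df = nlevels(droplevels(groups)) - 1, p_value = 1))
  }
  ht <- stats::kruskal.test(values, droplevels(groups))
  tibble::tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Pearson chi-square test on a contingency table
#'
#' No continuity correction; expected counts from the margins (delegates to
#' [stats::chisq.test()]).
#'
#' @param counts Integer matrix (groups x categories).
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("chi_square: zero row or column margin")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Fisher's exact test
#'
#' Exact p for small tables (grand total <= `exact_total`); otherwise a
#' seeded Monte Carlo estimate with its standard error (delegates to
#' [stats::fisher.test()]).
#'
#' @param counts Integer matrix (2 groups x up to 6 categories).
#' @param mc_reps Monte Carlo replicates for large tables.
#' @param seed Seed for the Monte Carlo path.
#' @param exact_total Largest grand total for the exact path.
#' @return One-row tibble: `p_value`, `mc_se` (`NA` on the exact path),
#'   `method`.
#' @export
fisher_exact <- function(counts, mc_reps = 1e5, seed = 1, exact_total = 200) {
  counts <- as.matrix(counts)
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  if (ncol(counts) < 2) stop("fisher_exact: degenerate single-category table")
  if (sum(counts) <= exact_total) {
    ht <- stats::fisher.test(counts, workspace = 2e7)
    tibble::tibble(p_value = ht$p.value, mc_se = NA_real_, method = "exact")
  } else {
    ht <- withr::with_seed(seed,
      stats::fisher.test(counts, simulate.p.value = TRUE, B = mc_reps))
    p <- ht$p.value
    tibble::tibble(p_value = p, mc_se = sqrt(p * (1 - p) / mc_reps),
                   method = sprintf("monte_carlo (B = %d)", as.integer(mc_reps)))
  }
}

# ---- paired change analysis -------------------------------------------------

.paired_wilcoxon_result <- function(paired, deltas, alternative, contrast) {
  wt <- if (length(deltas) >= 2) {
    wilcoxon_signed_rank(deltas, alternative = alternative)
  } else {
    tibble::tibble(statistic = NA_real_, n = length(deltas),
                   p_value = NA_real_, method = "undefined (< 2 replicates)")
  }
  n <- length(deltas)
  pct <- function(k) if (n == 0) NA_real_ else round(100 * k / n)
  structure(
    list(
      data = paired,
      contrast = contrast,
      n_replicates = n,
      wilcoxon_statistic = wt$statistic,
      p_value = wt$p_value,
      method = wt$method,
      alternative = alternative,
      pct_declined = pct(sum(deltas < 0)),
      pct_increased = pct(sum(deltas > 0)),
      pct_unchanged = pct(sum(deltas == 0))
    ),
    class = "oyster_change"
  )
}

#' Paired temporal change in an index across estuaries
#'
#' Compares the pre-2000 and post-2000 value of an index with each estuary as
#' a replicate, via a paired Wilcoxon signed-rank test on the per-estuary
#' differences (post minus pre). Only estuaries with a defined index and at
#' least `min_records` records in both periods enter.
#'
#' @param pre,post Index tibbles from [indices_by_estuary()] for the two
#'   periods (same species and index type).
#' @param min_records Minimum records per period per estuary (default 3).
#' @param alternative Sidedness for the Wilcoxon test (default two-sided).
#' @return An `oyster_change` object; see [tidy.oyster_change()] and
#'   [glance.oyster_change()]. Percentages of estuaries declining,
#'   increasing, and unchanged are rounded to integer percent.
#' @export
paired_change <- function(pre, post, min_records = 3,
                          alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  paired <- dplyr::inner_join(
    dplyr::select(pre, "estuary_id", pre = "value", n_pre = "n_records"),
    dplyr::select(post, "estuary_id", post = "value", n_post = "n_records"),
    by = "estuary_id"
  ) %>%
    dplyr::filter(!is.na(.data$pre), !is.na(.data$post),
                  .data$n_pre >= min_records, .data$n_post >= min_records) %>%
    dplyr::mutate(delta = .data$post - .data$pre)
  .paired_wilcoxon_result(paired, paired$delta, alternative,
                          contrast = "post2000 - pre2000")
}

#' Paired between-species comparison of an index
#'
#' Compares two species within the same estuaries and period via a paired
#' Wilcoxon test; an estuary enters only if both species have a defined index
#' with at least `min_records` records.
#'
#' @param a,b Index tibbles for the two species (same period and index type);
#'   differences are `a - b`.
#' @inheritParams paired_change
#' @return An `oyster_change` object.
#' @export
species_paired_comparison <- function(a, b, min_records = 3,
                                      alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  sp_a <- if ("species" %in% names(a)) unique(a$species) else "a"
  sp_b <- if ("species" %in% names(b)) unique(b$species) else "b"
  paired <- dplyr::inner_join(
    dplyr::select(a, "estuary_id", pre = "value", n_pre = "n_records"),
    dplyr::select(b, "estuary_id", post = "value", n_post = "n_records"),
    by = "estuary_id"
  ) %>%
    dplyr::filter(!is.na(.data$pre), !is.na(.data$post),
                  .data$n_pre >= min_records, .data$n_post >= min_records) %>%
    dplyr::mutate(delta = .data$pre - .data$post) %>%
    dplyr::rename(value_a = "pre", value_b = "post",
                  n_a = "n_pre", n_b = "n_post")
  .paired_wilcoxon_result(paired, paired$delta, alternative,
                          contrast = paste(sp_a[1], "-", sp_b[1]))
}

#' @export
print.oyster_change <- function(x, ...) {
  cat("Paired Wilcoxon change analysis (", x$contrast, ")\n", sep = "")
  cat(sprintf("  replicates (estuaries): %d\n", x$n_replicates))
  cat(sprintf("  V = %s, p = %s  [%s]\n",
              format(x$wilcoxon_statistic), format.pval(x$p_value), x$method))
  cat(sprintf("  declined %s%%, increased %s%%, unchanged %s%%\n",
              x$pct_declined, x$pct_increased, x$pct_unchanged))
  invisible(x)
}

#' Tidy a paired change analysis
#'
#' @param x An `oyster_change` object.
#' @param ... Unused.
#' @return `tidy()`: the per-estuary paired values and differences.
#'   `glance()`: a one-row tibble with the test statistic, p-value, replicate
#'   count, and change percentages.
#' @export
tidy.oyster_change <- function(x, ...) {
  tibble::as_tibble(x$data)
}

#' @rdname tidy.oyster_change
#' @export
glance.oyster_change <- function(x, ...) {
  tibble::tibble(
    contrast = x$contrast, n_replicates = x$n_replicates,
    statistic = x$wilcoxon_statistic, p_value = x$p_value,
    pct_declined = x$pct_declined, pct_increased = x$pct_increased,
    pct_unchanged = x$pct_unchanged, method = x$method
  )
}
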