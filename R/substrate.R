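# Substrate use and selection analysis.
#
# Substrate classes (by approximate mean diameter): riprap/boulder (>25 cm),
# cobble (5-25 cm), gravel/pebble (0.6-5 cm), sandflat/mudflat,
# seawall/dock/piling, and other anthropogenic structure. Use is compared
# across regions and species with contingency tests, and against
# availability with the selection index w_i = u_i / p_i, where values >1
# mean a habitat is used proportionally more than available.

#' Substrate use counts
#'
#' Counts presence records per group (region or species) per substrate class
#' for one period. Records with unknown substrate are excluded and tallied in
#' the `n_excluded` attribute.
#'
#' @param records Record tibble (needs a `region` column when grouping by
#'   region).
#' @param grouping `"by_region"` or `"by_species"`.
#' @param period Analysis period (default `"post2000"`, the current window).
#' @return Tibble with a `group` column and one integer column per substrate
#'   class; attribute `n_excluded` counts unknown-substrate records.
#' @export
substrate_counts <- function(records, grouping = c("by_region", "by_species"),
                             period = "post2000") {
  grouping <- match.arg(grouping)
  use <- records %>%
    dplyr::filter(.data$abundance_class %in% presence_classes,
                  assign_period(.data$year) %in% period)
  n_excluded <- sum(use$substrate_class == "unknown" | is.na(use$substrate_class))
  use <- dplyr::filter(use, .data$substrate_class %in% substrate_classes)
  group_col <- if (grouping == "by_region") "region" else "species"
  tab <- use %>%
    dplyr::count(group = .data[[group_col]], .data$substrate_class) %>%
    tidyr::pivot_wider(names_from = "substrate_class", values_from = "n",
                       values_fill = 0L)
  for (cls in substrate_classes) {
    if (!cls %in% names(tab)) tab[[cls]] <- 0L
  }
  tab <- dplyr::select(tab, "group", dplyr::all_of(substrate_classes))
  structure(tab, n_excluded = n_excluded)
}

#' Drop sparsely observed groups from a use table
#'
#' Removes groups (regions) having fewer than `min_count` observations in
#' any substrate category, the sparseness rule applied before the regional
#' chi-square comparison.
#'
#' @param table Use table from [substrate_counts()].
#' @param min_count Minimum per-category count (default 5).
#' @return Filtered table; removed groups are named in a message. Errors if
#'   every group is removed.
#' @export
filter_regions <- function(table, min_count = 5) {
  counts <- as.matrix(table[, substrate_classes])
  keep <- apply(counts, 1, min) >= min_count
  if (!any(keep)) stop("filter_regions: all groups removed")
  if (any(!keep)) {
    message("filter_regions: removed ", paste(table$group[!keep], collapse = ", "))
  }
  table[keep, , drop = FALSE]
}

# counts matrix from a use table
use_matrix <- function(table) {
  m <- as.matrix(table[, substrate_classes])
  rownames(m) <- table$group
  m
}

#' Availability profile
#'
#' @param p Named numeric vector of availability proportions over the six
#'   substrate classes (must sum to 1).
#' @return Validated numeric vector ordered like [substrate_classes].
#' @export
availability_profile <- function(p) {
  stopifnot(all(substrate_classes %in% names(p)))
  p <- p[substrate_classes]
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-9)
  p
}

#' Habitat selection analysis
#'
#' Computes use proportions `u_i`, the selection index `w_i = u_i / p_i`
#' (values above 1 mean the habitat is used proportionally more than
#' available; `w_i = 0` when use is zero; undefined and flagged when
#' `p_i = 0` with use present), and simultaneous confidence intervals on
#' `u_i`. If availability `p_i` falls outside the interval for use, the
#' habitat is classified as preferred (below the interval) or avoided (above
#' it); otherwise use is proportional to availability.
#'
#' Intervals are Bonferroni-adjusted normal-approximation intervals on the
#' use proportions (z at `alpha / (2k)` for `k` classes, the selection-ratio
#' convention); Wilson score intervals with the same adjustment are available
#' via `ci_method = "wilson"`.
#'
#' @param use_counts Named integer vector of use counts per substrate class.
#' @param availability An [availability_profile()].
#' @param alpha Familywise error rate (default 0.05 for 95% simultaneous
#'   intervals).
#' @param ci_method `"bonferroni"` (normal approximation) or `"wilson"`.
#' @return Tibble of class `oyster_selection`: `habitat`, `use_count`, `u_i`,
#'   `p_i`, `w_i`, `ci_low`, `ci_high`, `call`.
#' @export
selection_analysis <- function(use_counts, availability, alpha = 0.05,
                               ci_method = c("bonferroni", "wilson")) {
  ci_method <- match.arg(ci_method)
  availability <- availability_profile(availability)
  stopifnot(all(substrate_classes %in% names(use_counts)))
  u_counts <- as.numeric(use_counts[substrate_classes])
  n <- sum(u_counts)
  stopifnot(n >= 1)
  u <- u_counts / n
  p <- as.numeric(availability)
  w <- ifelse(u == 0, 0, ifelse(p == 0, NA_real_, u / p))
  if (any(u > 0 & p == 0)) {
    warning("selection_analysis: use recorded on habitat with zero availability; w_i undefined there")
  }
  k <- length(substrate_classes)
  z <- stats::qnorm(1 - alpha / (2 * k))
  if (ci_method == "bonferroni") {
    half <- z * sqrt(u * (1 - u) / n)
    lo <- pmax(0, u - half)
    hi <- pmin(1, u + half)
  } else {
    denom <- 1 + z^2 / n
    center <- (u + z^2 / (2 * n)) / denom
    half <- z * sqrt(u * (1 - u) / n + z^2 / (4 * n^2)) / denom
    lo <- pmax(0, center - half)
    hi <- pmin(1, center + half)
  }
  call <- dplyr::case_when(
    p < lo ~ "preference",
    p > hi ~ "avoidance",
    TRUE ~ "proportional"
  )
  structure(
    tibble::tibble(habitat = substrate_classes, use_count = as.integer(u_counts),
                   u_i = u, p_i = p, w_i = w, ci_low = lo, ci_high = hi,
                   call = call),
    class = c("oyster_selection", class(tibble::tibble()))
  )
}
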