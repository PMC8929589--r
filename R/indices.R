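# Per-estuary distribution and abundance indices.
#
# Distribution index: presence records / (presence + absence) records for a
# species in an estuary; 0 means all records were absences, 1 means no
# absence records. Sensitive to search effort, since absence reporting grew
# over time.
#
# Abundance index: common records / (common + rare) records; records that
# are merely "present" carry no abundance information and are excluded from
# both numerator and denominator. Undefined when no abundance-informative
# records exist (propagated as NA, never as 0 - zero is a meaningful value).

.index_value <- function(records, index_type) {
  ab <- records$abundance_class
  if (index_type == "distribution") {
    n <- length(ab)
    value <- if (n == 0) NA_real_ else sum(ab %in% presence_classes) / n
  } else {
    n <- sum(ab %in% c("common", "rare"))
    value <- if (n == 0) NA_real_ else sum(ab == "common") / n
  }
  list(value = value, n_records = as.integer(n))
}

#' Distribution and abundance index for one estuary cell
#'
#' Computes one index from the records of a single estuary x species x
#' period cell.
#'
#' @param records Record tibble (all rows assumed to share estuary, species,
#'   and period).
#' @return One-row tibble with `index_type`, `value` (`NA` when undefined),
#'   and `n_records` (the size of the index's own denominator).
#' @export
distribution_index <- function(records) {
  v <- .index_value(records, "distribution")
  tibble::tibble(index_type = "distribution", value = v$value,
                 n_records = v$n_records)
}

#' @rdname distribution_index
#' @export
abundance_index <- function(records) {
  v <- .index_value(records, "abundance")
  tibble::tibble(index_type = "abundance", value = v$value,
                 n_records = v$n_records)
}

#' Index values for every estuary
#'
#' Computes the chosen index per estuary x species for one period, keeping
#' only estuaries whose index denominator holds at least `min_records`
#' records (the replicate filter used throughout the change analyses).
#' Records with no estuary (open coast) or outside the period are excluded.
#'
#' @param records Record tibble with `estuary_id` and `year` columns.
#' @param index_type `"distribution"` or `"abundance"`.
#' @param period `"pre2000"` or `"post2000"`.
#' @param min_records Minimum denominator size (default 3).
#' @return Tibble: `estuary_id`, `species`, `period`, `index_type`, `value`,
#'   `n_records`.
#' @export
indices_by_estuary <- function(records, index_type = c("distribution", "abundance"),
                               period = c("post2000", "pre2000"), min_records = 3) {
  index_type <- match.arg(index_type)
  period <- match.arg(period)
  out <- records %>%
    dplyr::filter(!is.na(.data$estuary_id),
                  assign_period(.data$year) %in% period) %>%
    dplyr::group_by(.data$estuary_id, .data$species) %>%
    dplyr::group_modify(function(df, key) {
      v <- .index_value(df, index_type)
      tibble::tibble(value = v$value, n_records = v$n_records)
    }) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(period = period, index_type = index_type) %>%
    dplyr::select("estuary_id", "species", "period", "index_type",
                  "value", "n_records")
  dropped <- dplyr::filter(out, .data$n_records < min_records)
  if (nrow(dropped) > 0) {
    message(sprintf("indices_by_estuary: %d estuary x species cell(s) below %d records omitted",
                    nrow(dropped), min_records))
  }
  dplyr::filter(out, .data$n_records >= min_records)
}

#' Count estuaries where a species is documented present
#'
#' The number of distinct estuaries with at least one presence record for a
#' species in a period (the estuary-occupancy count).
#'
#' @param records Record tibble with `estuary_id`.
#' @param species Species label.
#' @param period `"pre2000"` or `"post2000"`.
#' @return Integer count.
#' @export
estuaries_present_count <- function(records, species, period = "post2000") {
  sp <- species
  records %>%
    dplyr::filter(.data$species == sp,
                  assign_period(.data$year) %in% period,
                  .data$abundance_class %in% presence_classes,
                  !is.na(.data$estuary_id)) %>%
    dplyr::distinct(.data$estuary_id) %>%
    nrow()
}
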