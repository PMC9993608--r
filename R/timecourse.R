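#' Interval-normalised DEG rates along a time course
#'
#' Given DEG tables for a fixed reference against successive time points,
#' tallies up/down/total DEG counts and normalises them by elapsed time.
#' Two variants are emitted: `rate_cumulative` divides the total DEG count
#' by the elapsed time since the reference (the figure-legend reading of
#' "normalised by the number of interval days/hours"), and
#' `rate_incremental` divides the change in DEG count by the gap to the
#' previous time point (this variant drives [transition_window()]).
#'
#' @param deg_tables List of [call_degs()] results sharing a reference
#'   condition, one per time point.
#' @param design Sample design supplying `time_value` per condition.
#' @return A `rate_series` tibble ordered by time: `condition`,
#'   `time_value`, `n_up`, `n_down`, `n_total`, `delta_time`,
#'   `rate_cumulative`, `rate_incremental`.
#' @export
rate_series <- function(deg_tables, design) {
  design <- validate_design(design)
  contrasts <- lapply(deg_tables, attr, "contrast")
  refs <- vapply(contrasts, `[`, "", 1)
  if (length(unique(refs)) != 1) {
    abort("all DEG tables must share the same reference condition")
  }
  conds <- vapply(contrasts, `[`, "", 2)
  tv <- design$time_value[match(conds, design$condition)]
  if (anyNA(tv)) abort("contrast condition absent from design")
  if (anyDuplicated(tv) || anyDuplicated(conds)) {
    abort("duplicate time points in rate series")
  }
  ord <- order(tv)
  conds <- conds[ord]; tv <- tv[ord]; deg_tables <- deg_tables[ord]
  if (any(tv <= 0)) abort("time values must be positive relative to reference")

  n_up <- vapply(deg_tables, function(d) sum(d$call == "up"), 0L)
  n_down <- vapply(deg_tables, function(d) sum(d$call == "down"), 0L)
  n_total <- n_up + n_down
  delta_t <- diff(c(0, tv))
  out <- tibble::tibble(
    condition = conds,
    time_value = tv,
    n_up = n_up,
    n_down = n_down,
    n_total = n_total,
    delta_time = delta_t,
    rate_cumulative = n_total / tv,
    rate_incremental = diff(c(0L, n_total)) / delta_t
  )
  attr(out, "reference") <- refs[1]
  class(out) <- c("rate_series", class(out))
  out
}

#' Fraction of DEGs retained at the next time point
#'
#' For consecutive DEG tables against a common reference, the fraction of
#' each time point's called genes (up or down) that are called again at the
#' next time point. An empty DEG set yields `NA`.
#'
#' @param deg_tables Ordered list of >= 2 [call_degs()] results sharing a
#'   reference.
#' @return A tibble: `from_condition`, `to_condition`, `n_from`,
#'   `n_retained`, `fraction`.
#' @export
retention_fraction <- function(deg_tables) {
  if (length(deg_tables) < 2) abort("need >= 2 DEG tables")
  contrasts <- lapply(deg_tables, attr, "contrast")
  refs <- vapply(contrasts, `[`, "", 1)
  if (length(unique(refs)) != 1) {
    abort("all DEG tables must share the same reference condition")
  }
  conds <- vapply(contrasts, `[`, "", 2)
  sets <- lapply(deg_tables, deg_genes)
  k <- length(sets) - 1
  tibble::tibble(
    from_condition = conds[seq_len(k)],
    to_condition = conds[seq_len(k) + 1],
    n_from = vapply(seq_len(k), function(i) length(sets[[i]]), 0L),
    n_retained = vapply(seq_len(k), function(i) {
      length(intersect(sets[[i]], sets[[i + 1]]))
    }, 0L),
  ) |>
    dplyr::mutate(fraction = ifelse(.data$n_from == 0, NA_real_,
                                    .data$n_retained / .data$n_from))
}

#' Localise the transition window of a rate series
#'
#' Returns the consecutive pair of time points with the maximal positive
#' increase in the incremental normalised DEG rate — the window in which
#' expression turnover accelerates most, used to date the end of diapause.
#' Ties break toward the earlier pair. If no increment is positive, a
#' none-sentinel row (`NA` conditions) is returned with a warning.
#'
#' @param rates A [rate_series()] with >= 3 time points.
#' @return A one-row tibble: `from_condition`, `to_condition`,
#'   `rate_increase`.
#' @export
transition_window <- function(rates) {
  if (nrow(rates) < 3) abort("transition window needs >= 3 time points")
  incr <- diff(rates$rate_incremental)
  if (all(incr <= 0)) {
    warn("no positive increase in incremental DEG rate; no transition window")
    return(tibble::tibble(from_condition = NA_character_,
                          to_condition = NA_character_,
                          rate_increase = NA_real_))
  }
  k <- which.max(incr)  # first maximum -> earlier pair on ties
  tibble::tibble(
    from_condition = rates$condition[k],
    to_condition = rates$condition[k + 1],
    rate_increase = incr[k]
  )
}
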