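#' Condition vocabularies for the diapause / reactivation time courses
#'
#' The storage (diapause-entry) series compares blastoderms from freshly
#' oviposited eggs (`F0`) with eggs stored below physiological zero for 1, 2,
#' 4, 8 or 12 days (`S1d`-`S12d`; time in days). The incubation (reactivation)
#' series returns 2-day-stored eggs (`S2d`) to 37.8 C for 0.5-12 hours
#' (`In0.5h`-`In12h`; time in hours). Time units are fixed per series and
#' never converted: DEG rates are normalised by interval days for storage and
#' interval hours for incubation.
#'
#' @return A tibble with columns `condition`, `series` (`"storage"` or
#'   `"incubation"`) and `time_value` (days or hours, per series), in
#'   chronological order within each series.
#' @export
#' @examples
#' condition_table()
condition_table <- function() {
  tibble::tibble(
    condition  = c("F0", "S1d", "S2d", "S4d", "S8d", "S12d",
                   "In0.5h", "In1h", "In2h", "In4h", "In6h", "In12h"),
    series     = c(rep("storage", 6), rep("incubation", 6)),
    time_value = c(0, 1, 2, 4, 8, 12, 0.5, 1, 2, 4, 6, 12)
  )
}

storage_conditions <- function() {
  ct <- condition_table()
  ct$condition[ct$series == "storage"]
}

incubation_conditions <- function() {
  ct <- condition_table()
  ct$condition[ct$series == "incubation"]
}

#' Build a sample-design table for the standard time course
#'
#' @param conditions Character vector of condition labels; defaults to the
#'   full storage + incubation course.
#' @param n_replicates Replicates per condition (default 3, as in typical
#'   pooled-blastoderm RNA-seq designs).
#' @return A tibble with columns `sample_id`, `condition`, `replicate`,
#'   `time_value` and `series`.
#' @export
#' @examples
#' diapause_design(c("F0", "S1d", "S2d"), n_replicates = 3)
diapause_design <- function(conditions = condition_table()$condition,
                            n_replicates = 3) {
  ct <- condition_table()
  unknown <- setdiff(conditions, ct$condition)
  if (length(unknown) > 0) {
    abort(paste0("unknown condition(s): ", paste(unknown, collapse = ", ")))
  }
  des <- tidyr::expand_grid(
    condition = conditions,
    replicate = seq_len(n_replicates)
  )
  des <- dplyr::left_join(des, ct, by = "condition")
  des <- dplyr::mutate(des,
    sample_id = paste0(.data$condition, "_r", .data$replicate),
    .before = 1
  )
  validate_design(des)
}

#' Validate a sample-design table
#'
#' Checks column presence and types, unique sample identifiers, and that
#' `time_value` is constant within a condition and strictly increasing along
#' each series' declared condition order.
#'
#' @param design A data frame with columns `sample_id`, `condition`,
#'   `replicate`, `time_value`, `series`.
#' @return The design as a tibble, invisibly validated.
#' @export
validate_design <- function(design) {
  design <- tibble::as_tibble(design)
  needed <- c("sample_id", "condition", "replicate", "time_value", "series")
  miss <- setdiff(needed, names(design))
  if (length(miss) > 0) {
    abort(paste0("design is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(design$sample_id)) {
    abort("design sample_id values must be unique")
  }
  if (!all(design$series %in% c("storage", "incubation"))) {
    abort("design series must be 'storage' or 'incubation'")
  }
  if (any(design$time_value < 0) || any(!is.finite(design$time_value))) {
    abort("design time_value must be finite and non-negative")
  }
  if (any(design$replicate < 1)) {
    abort("design replicate indices must be positive")
  }
  per_cond <- dplyr::distinct(design, .data$condition, .data$time_value)
  if (anyDuplicated(per_cond$condition)) {
    abort("time_value must be constant within a condition")
  }
  # strictly increasing along each series in declared condition order
  ord <- condition_table()
  for (ser in unique(design$series)) {
    conds <- ord$condition[ord$series == ser & ord$condition %in% design$condition]
    tv <- per_cond$time_value[match(conds, per_cond$condition)]
    if (length(tv) > 1 && any(diff(tv) <= 0)) {
      abort(paste0("time_value not strictly increasing along ", ser, " series"))
    }
  }
  design
}

# samples belonging to one condition, in design order
condition_samples <- function(design, condition) {
  ids <- design$sample_id[design$condition == condition]
  if (length(ids) == 0) {
    abort(paste0("condition '", condition, "' absent from design"))
  }
  ids
}
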