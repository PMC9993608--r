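#' Fold-change reversal regression for one reactivation time point
#'
#' Over a DEG set from the diapause contrast (F0 vs S2d), regresses the
#' reactivation fold change on the diapause fold change. Per gene,
#' `x = log2(mean_F0 / mean_S2d)` and `y = log2(mean_In / mean_S2d)`
#' (condition-mean expression, pseudo-count 0.5): a slope near 0 means
#' expression is still at the diapause level, a slope near 1 means full
#' recovery of the pre-diapause state. Ordinary least squares of y on x;
#' the p-value is the two-sided test of zero Pearson correlation.
#'
#' @param deg_set Character vector of gene ids (typically
#'   `deg_genes()` of the F0-vs-S2d contrast).
#' @param expr Wide expression tibble (FPKM or CPM).
#' @param design Sample design covering F0, S2d and the incubation
#'   condition.
#' @param incubation_condition Condition label, e.g. `"In4h"`.
#' @param pseudo_count Added to condition means before log2. Default 0.5.
#' @return An object of class `reversal_fit` with fields
#'   `incubation_condition`, `n`, `pearson_r`, `slope`, `intercept`,
#'   `p_value` and the per-gene `data` tibble. Has [tidy()]/[glance()]
#'   methods and an [autoplot()].
#' @export
reversal_fit <- function(deg_set, expr, design, incubation_condition,
                         pseudo_count = 0.5) {
  if (length(deg_set) == 0) abort("deg_set is empty")
  design <- validate_design(design)
  cm <- condition_means(expr, design,
                        c("F0", "S2d", incubation_condition))
  genes <- intersect(deg_set, rownames(cm))
  if (length(genes) < 3) {
    abort("fewer than 3 DEG-set genes present in the expression matrix")
  }
  x <- log2(cm[genes, "F0"] + pseudo_count) -
    log2(cm[genes, "S2d"] + pseudo_count)
  y <- log2(cm[genes, incubation_condition] + pseudo_count) -
    log2(cm[genes, "S2d"] + pseudo_count)
  fit <- lm(y ~ x)
  ct <- suppressWarnings(cor.test(x, y))
  structure(
    list(
      incubation_condition = incubation_condition,
      n = length(genes),
      pearson_r = unname(ct$estimate),
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      p_value = ct$p.value,
      data = tibble::tibble(gene_id = genes, x = unname(x), y = unname(y))
    ),
    class = "reversal_fit"
  )
}

#' @export
print.reversal_fit <- function(x, ...) {
  cat(sprintf(
    "<reversal_fit> %s: n = %d, R = %.3f, slope = %.3f, p = %.3g\n",
    x$incubation_condition, x$n, x$pearson_r, x$slope, x$p_value
  ))
  invisible(x)
}

#' @export
tidy.reversal_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @export
glance.reversal_fit <- function(x, ...) {
  tibble::tibble(
    incubation_condition = x$incubation_condition,
    n = x$n, pearson_r = x$pearson_r, slope = x$slope,
    intercept = x$intercept, p_value = x$p_value
  )
}

#' Slope trajectory across reactivation time points
#'
#' Orders reversal fits by incubation time and flags whether the recovery
#' slope is monotone non-decreasing — the signature of progressive return
#' toward the pre-diapause expression state.
#'
#' @param fits List of >= 2 [reversal_fit()] objects.
#' @return A tibble `condition`, `time_value`, `slope` (ordered by time)
#'   with attribute `monotone`.
#' @export
slope_trajectory <- function(fits) {
  if (length(fits) < 2) abort("slope trajectory needs >= 2 fits")
  stopifnot(all(vapply(fits, inherits, TRUE, "reversal_fit")))
  ct <- condition_table()
  conds <- vapply(fits, function(f) f$incubation_condition, "")
  tv <- ct$time_value[match(conds, ct$condition)]
  if (anyNA(tv)) abort("unknown incubation condition in fits")
  ord <- order(tv)
  out <- tibble::tibble(
    condition = conds[ord],
    time_value = tv[ord],
    slope = vapply(fits, function(f) f$slope, 0)[ord]
  )
  attr(out, "monotone") <- !is.unsorted(out$slope)
  out
}

#' Gene-set fold-change summary with a random-gene control
#'
#' For each contrast, computes per-gene log10 fold changes of
#' pseudo-counted condition-mean expression, then the median and mean over
#' an annotated gene set, alongside the same summaries for a control set of
#' `config$control_set_size` genes sampled uniformly without replacement
#' from the expressed genes outside the set (seeded by `config$rng_seed`).
#'
#' @param annotation Gene-set tibble (`term_id`, `term_name`, `gene_id`)
#'   holding one term.
#' @param expr Wide expression tibble.
#' @param design Sample design.
#' @param contrasts List of `c(reference, condition)` pairs.
#' @param config A [run_config()].
#' @param pseudo_count Added to condition means. Default 0.5.
#' @return A tibble, one row per contrast: `term_id`, `contrast`,
#'   `n_genes`, `median_log10fc`, `mean_log10fc`, `n_control`,
#'   `control_median`, `control_mean`.
#' @export
gene_set_fc_summary <- function(annotation, expr, design, contrasts,
                                config = run_config(), pseudo_count = 0.5) {
  annotation <- validate_gene_sets(annotation)
  term <- unique(annotation$term_id)
  if (length(term) != 1) abort("annotation must hold exactly one term")
  design <- validate_design(design)
  all_conds <- unique(unlist(contrasts))
  cm <- condition_means(expr, design, all_conds)
  expressed <- rownames(cm)
  set_genes <- intersect(annotation$gene_id, expressed)
  if (length(set_genes) < 3) {
    abort(paste0("term '", term, "': fewer than 3 genes in expression matrix"))
  }
  pool <- setdiff(expressed, set_genes)
  n_ctl <- min(config$control_set_size, length(pool))
  control_genes <- with_seed(config$rng_seed, sample(pool, n_ctl))

  purrr::map_dfr(contrasts, function(ctr) {
    fc <- log10(cm[, ctr[2]] + pseudo_count) -
      log10(cm[, ctr[1]] + pseudo_count)
    tibble::tibble(
      term_id = term,
      contrast = paste(ctr[1], "vs", ctr[2]),
      n_genes = length(set_genes),
      median_log10fc = median(fc[set_genes]),
      mean_log10fc = mean(fc[set_genes]),
      n_control = n_ctl,
      control_median = median(fc[control_genes]),
      control_mean = mean(fc[control_genes])
    )
  })
}
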