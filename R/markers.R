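#' Screen for temperature-responsive diapause marker genes
#'
#' A candidate is an up-marker if, on condition-mean expression:
#' (i) every storage condition (S1d-S12d) is strictly higher than F0;
#' (ii) no incubation condition up to In4h is higher than S2d (non-strict);
#' (iii) the In4h level is similar to F0 — `|log2(mean_In4h / mean_F0)| <
#' similarity_tolerance` — and the gene is not a DEG in the In4h-vs-F0
#' contrast. Down-markers mirror the inequalities. Every sub-check is
#' recorded; a candidate missing from the expression matrix is recorded as
#' a failure, not an error.
#'
#' @param candidates Character vector of candidate gene ids (typically the
#'   called DEGs of F0-vs-S1d).
#' @param expr Wide expression tibble covering F0, the storage conditions
#'   and the incubation conditions through In4h.
#' @param design Sample design.
#' @param deg_in4h_vs_f0 [call_degs()] table for the F0-vs-In4h contrast
#'   (used by condition iii), or `NULL` to skip the DEG part of (iii).
#' @param config A [run_config()]; supplies `similarity_tolerance`.
#' @param pseudo_count Added to condition means before log2 ratios.
#' @return A tibble, one row per candidate: `gene_id`, `direction`
#'   (`up_candidate` / `down_candidate` / `fail`), `cond_i_pass`,
#'   `cond_ii_pass`, `cond_iii_pass` (for the evaluated direction),
#'   `mean_f0`, `mean_s2d`, `mean_in4h`, `log2_in4h_vs_f0`.
#' @export
screen_markers <- function(candidates, expr, design, deg_in4h_vs_f0 = NULL,
                           config = run_config(), pseudo_count = 0.5) {
  design <- validate_design(design)
  storage <- intersect(storage_conditions(), unique(design$condition))
  storage <- setdiff(storage, "F0")
  if (length(storage) == 0) abort("design has no storage conditions")
  inc_all <- intersect(incubation_conditions(), unique(design$condition))
  ct <- condition_table()
  t_in4h <- ct$time_value[ct$condition == "In4h"]
  inc <- inc_all[ct$time_value[match(inc_all, ct$condition)] <= t_in4h]
  needed <- c("F0", "S2d", "In4h")
  miss <- setdiff(needed, unique(design$condition))
  if (length(miss) > 0) {
    abort(paste0("marker screen requires condition(s): ",
                 paste(miss, collapse = ", ")))
  }
  cm <- condition_means(expr, design, unique(c("F0", storage, inc)))

  deg_in4h <- if (is.null(deg_in4h_vs_f0)) character(0) else {
    deg_genes(deg_in4h_vs_f0)
  }
  tol <- config$similarity_tolerance

  rows <- purrr::map_dfr(candidates, function(g) {
    if (!g %in% rownames(cm)) {
      return(tibble::tibble(
        gene_id = g, direction = "fail",
        cond_i_pass = FALSE, cond_ii_pass = FALSE, cond_iii_pass = FALSE,
        mean_f0 = NA_real_, mean_s2d = NA_real_, mean_in4h = NA_real_,
        log2_in4h_vs_f0 = NA_real_, reason = "absent from expression matrix"
      ))
    }
    v <- cm[g, ]
    l2_in4h <- log2(v[["In4h"]] + pseudo_count) -
      log2(v[["F0"]] + pseudo_count)
    iii <- abs(l2_in4h) < tol && !(g %in% deg_in4h)

    eval_dir <- function(up) {
      s_ok <- if (up) all(v[storage] > v[["F0"]]) else
        all(v[storage] < v[["F0"]])
      i_ok <- if (up) all(v[inc] <= v[["S2d"]]) else
        all(v[inc] >= v[["S2d"]])
      c(i = s_ok, ii = i_ok)
    }
    up <- eval_dir(TRUE); down <- eval_dir(FALSE)
    if (all(up) && iii) {
      dir <- "up_candidate"; checks <- c(up, iii = TRUE)
    } else if (all(down) && iii) {
      dir <- "down_candidate"; checks <- c(down, iii = TRUE)
    } else {
      dir <- "fail"
      # report the direction suggested by the mean storage offset
      sugg_up <- mean(v[storage]) >= v[["F0"]]
      checks <- c(if (sugg_up) up else down, iii = iii)
    }
    tibble::tibble(
      gene_id = g, direction = dir,
      cond_i_pass = unname(checks["i"]),
      cond_ii_pass = unname(checks["ii"]),
      cond_iii_pass = unname(checks["iii"]),
      mean_f0 = v[["F0"]], mean_s2d = v[["S2d"]], mean_in4h = v[["In4h"]],
      log2_in4h_vs_f0 = unname(l2_in4h), reason = NA_character_
    )
  })
  class(rows) <- c("marker_report", class(rows))
  rows
}

#' Tally DEG direction against proliferation-regulation annotation
#'
#' Cross-tabulates up/down DEGs with gene sets for negative and positive
#' regulation of cell proliferation. The `direction_consistent` flag is true
#' when the (continuity-corrected) odds ratio of up-DEGs falling in the
#' negative-regulation set exceeds 1 — the proliferation-arrest signature in
#' which genes preventing proliferation are activated and genes promoting
#' it are repressed.
#'
#' @param deg A [call_degs()] table.
#' @param negative_set,positive_set Gene-set tibbles (`term_id`,
#'   `term_name`, `gene_id`).
#' @return A one-row tibble with the annotated set sizes, the four
#'   intersection counts, `odds_ratio` and `direction_consistent`.
#' @export
proliferation_tally <- function(deg, negative_set, positive_set) {
  negative_set <- validate_gene_sets(negative_set)
  positive_set <- validate_gene_sets(positive_set)
  up <- deg$gene_id[deg$call == "up"]
  down <- deg$gene_id[deg$call == "down"]
  neg <- unique(negative_set$gene_id)
  pos <- unique(positive_set$gene_id)
  up_neg <- length(intersect(up, neg))
  up_pos <- length(intersect(up, pos))
  down_neg <- length(intersect(down, neg))
  down_pos <- length(intersect(down, pos))
  or <- ((up_neg + 0.5) * (down_pos + 0.5)) /
    ((up_pos + 0.5) * (down_neg + 0.5))
  tibble::tibble(
    n_annotated_negative = length(neg),
    n_annotated_positive = length(pos),
    up_negative = up_neg, up_positive = up_pos,
    down_negative = down_neg, down_positive = down_pos,
    odds_ratio = or,
    direction_consistent = or > 1
  )
}

#' Relative qPCR quantification by the 2^-ddCt method
#'
#' `ddCt = (target_ct_trt - ref_ct_trt) - (target_ct_ctl - ref_ct_ctl)`;
#' relative expression is exactly `2^(-ddCt)`. Adding a constant to all four
#' Ct values leaves the result unchanged.
#'
#' @param target_ct_trt,ref_ct_trt Target and reference-gene (e.g. beta
#'   actin) Ct in the treatment sample.
#' @param target_ct_ctl,ref_ct_ctl The same in the control sample.
#' @return A one-row tibble: the four Ct values, `ddct`,
#'   `relative_expression`.
#' @export
#' @examples
#' ddct(25, 20, 24, 20)  # one extra cycle -> halved expression
ddct <- function(target_ct_trt, ref_ct_trt, target_ct_ctl, ref_ct_ctl) {
  cts <- c(target_ct_trt, ref_ct_trt, target_ct_ctl, ref_ct_ctl)
  if (any(!is.finite(cts)) || any(cts <= 0) || any(cts >= 45)) {
    abort("Ct values must lie in (0, 45)")
  }
  dd <- (target_ct_trt - ref_ct_trt) - (target_ct_ctl - ref_ct_ctl)
  tibble::tibble(
    target_ct_trt = target_ct_trt, ref_ct_trt = ref_ct_trt,
    target_ct_ctl = target_ct_ctl, ref_ct_ctl = ref_ct_ctl,
    ddct = dd, relative_expression = 2^(-dd)
  )
}
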