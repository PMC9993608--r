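#' @name plots
#' @title Plot methods for diapausekit result types
#' @description `autoplot()` methods returning ggplot objects: DEG rate
#'   series (cumulative and incremental interval-normalised rates),
#'   reversal-fit scatter panels with the regression line, KSEA NES bars,
#'   and OPLS-DA score plots.
NULL

#' @rdname plots
#' @param object A `rate_series`, `reversal_fit`, `ksea_result` or `oplsda`
#'   object.
#' @param ... Unused.
#' @export
autoplot.rate_series <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("condition", "time_value",
                                "rate_cumulative", "rate_incremental")],
    cols = c("rate_cumulative", "rate_incremental"),
    names_to = "variant", values_to = "rate"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time_value, .data$rate,
                                     colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time since reference", y = "DEGs per interval unit",
                  colour = NULL)
}

#' @rdname plots
#' @export
autoplot.reversal_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "red") +
    ggplot2::labs(
      x = "log2 FC (F0 vs S2d)",
      y = paste0("log2 FC (", object$incubation_condition, " vs S2d)"),
      title = sprintf("%s: R = %.2f, slope = %.2f",
                      object$incubation_condition, object$pearson_r,
                      object$slope)
    )
}

#' @rdname plots
#' @export
autoplot.ksea_result <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$kinase_id <- factor(d$kinase_id, levels = rev(d$kinase_id))
  ggplot2::ggplot(d, ggplot2::aes(.data$nes, .data$kinase_id,
                                  fill = .data$perm_p < 0.05)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "normalised enrichment score", y = NULL,
                  fill = "perm p < 0.05")
}

#' @rdname plots
#' @export
autoplot.oplsda <- function(object, ...) {
  d <- tibble::tibble(
    t_pred = unname(object$t_pred),
    t_orth = if (object$n_orthogonal > 0) object$t_orth[, 1] else 0,
    group = ifelse(object$y > 0, object$group_levels[1],
                   object$group_levels[2])
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$t_pred, .data$t_orth,
                                  colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "predictive score", y = "orthogonal score")
}

#' Marker-style expression profile plot
#'
#' Condition-mean expression of selected genes across the storage and
#' incubation series, with the F0 level as a dashed reference line.
#'
#' @param expr Wide expression tibble.
#' @param design Sample design.
#' @param genes Character vector of gene ids.
#' @return A ggplot object faceted by gene.
#' @export
plot_marker_profiles <- function(expr, design, genes) {
  cm <- condition_means(expr, design)
  genes <- intersect(genes, rownames(cm))
  if (length(genes) == 0) abort("none of the genes are in the matrix")
  ct <- condition_table()
  d <- tidyr::expand_grid(gene_id = genes, condition = colnames(cm))
  d$mean_expr <- cm[cbind(d$gene_id, d$condition)]
  d <- dplyr::left_join(d, ct, by = "condition")
  d$condition <- factor(d$condition, levels = ct$condition)
  f0 <- tibble::tibble(gene_id = genes, level = cm[genes, "F0"])
  ggplot2::ggplot(d, ggplot2::aes(.data$condition, .data$mean_expr,
                                  group = .data$series,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(data = f0,
                        ggplot2::aes(yintercept = .data$level),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~gene_id, scales = "free_y") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
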