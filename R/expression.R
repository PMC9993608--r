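#' Normalised expression (CPM, FPKM or median-of-ratios)
#'
#' CPM divides each count by its sample's total and scales to one million;
#' FPKM additionally divides by gene length in kilobases:
#' `FPKM = counts * 1e9 / (library_size * length_bp)`. Both are
#' library-size units and inherit compositional shifts when strongly
#' regulated genes dominate a library; `"normalized"` divides counts by
#' median-of-ratios [size_factors()] instead, which is robust to
#' composition and preferred for cross-condition level comparisons such as
#' the marker screen.
#'
#' @param counts Wide count tibble (`gene_id` + sample columns).
#' @param lengths Named numeric vector of gene lengths in bp (required for
#'   FPKM; must cover every gene), or `NULL`.
#' @param unit `"CPM"`, `"FPKM"` or `"normalized"`.
#' @return A wide expression tibble with attribute `unit`.
#' @export
#' @examples
#' cts <- tibble::tibble(gene_id = c("a", "b"), s1 = c(90, 10))
#' compute_expression(cts, unit = "CPM")
compute_expression <- function(counts, lengths = NULL,
                               unit = c("CPM", "FPKM", "normalized")) {
  unit <- match.arg(unit)
  counts <- validate_counts(counts)
  m <- wide_to_matrix(counts, "gene_id")
  lib <- colSums(m)
  if (any(lib == 0)) {
    abort(paste0("sample(s) with zero total counts: ",
                 paste(colnames(m)[lib == 0], collapse = ", ")))
  }
  if (unit == "CPM") {
    e <- sweep(m, 2, lib, "/") * 1e6
  } else if (unit == "normalized") {
    e <- sweep(m, 2, size_factors(counts), "/")
  } else {
    if (is.null(lengths)) abort("FPKM requires a gene-length table")
    missing <- setdiff(rownames(m), names(lengths))
    if (length(missing) > 0) {
      abort(paste0("gene(s) missing from length table: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    len <- lengths[rownames(m)]
    if (any(!is.finite(len)) || any(len <= 0)) {
      abort("gene lengths must be positive")
    }
    e <- sweep(m * 1e9, 2, lib, "/") / len
  }
  out <- matrix_to_wide(e, "gene_id")
  attr(out, "unit") <- unit
  out
}

# condition-mean expression matrix: genes x conditions
condition_means <- function(expr, design, conditions = NULL) {
  m <- wide_to_matrix(expr, names(expr)[1])
  conditions <- conditions %||% unique(design$condition)
  out <- vapply(conditions, function(cond) {
    ids <- condition_samples(design, cond)
    missing <- setdiff(ids, colnames(m))
    if (length(missing) > 0) {
      abort(paste0("expression matrix missing sample(s): ",
                   paste(missing, collapse = ", ")))
    }
    rowMeans(m[, ids, drop = FALSE])
  }, numeric(nrow(m)))
  rownames(out) <- rownames(m)
  out
}
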