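# sample (intensity) columns of a phospho table
phospho_sample_cols <- function(phospho) {
  setdiff(names(phospho), c("peptide_id", "protein_id", "sites"))
}

#' Normalise phosphopeptide intensities
#'
#' Log2-transforms raw intensities, then subtracts each sample's median so
#' every sample has median exactly zero (median subtraction on the log
#' scale is ratio scaling on the raw scale). Tables already normalised (as
#' flagged by the `phospho_normalized` attribute) are only re-centred, so
#' the operation is idempotent.
#'
#' @param phospho Wide phospho tibble (`peptide_id`, `protein_id`, `sites`,
#'   one intensity column per sample).
#' @return The table with log2, median-centred intensities and attribute
#'   `phospho_normalized = TRUE`.
#' @export
normalize_phospho <- function(phospho) {
  phospho <- validate_phospho(phospho)
  cols <- phospho_sample_cols(phospho)
  m <- as.matrix(phospho[cols])
  if (!isTRUE(attr(phospho, "phospho_normalized"))) {
    bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort(paste0("non-positive intensity for peptide '",
                   phospho$peptide_id[bad[1, 1]], "', sample '",
                   cols[bad[1, 2]], "'"))
    }
    m <- log2(m)
  }
  m <- sweep(m, 2, apply(m, 2, median), "-")
  out <- phospho
  out[cols] <- tibble::as_tibble(m, .name_repair = "minimal")
  attr(out, "phospho_normalized") <- TRUE
  out
}

#' Call regulated phosphopeptides between two conditions
#'
#' On normalised (log2) intensities: `log2fc` is the difference of condition
#' means (second contrast condition minus reference); the p-value is a
#' two-sample, two-sided pooled-variance Student t-test. A peptide is
#' regulated iff `|log2fc| > log2(phospho_fc_threshold)` (strict) and
#' `p < phospho_p_threshold`.
#'
#' @param phospho Normalised phospho tibble ([normalize_phospho()]).
#' @param design Two-condition design with >= 3 replicates each.
#' @param config A [run_config()].
#' @param contrast Optional `c(reference, condition)`; defaults to the two
#'   conditions in design order.
#' @return A tibble: `peptide_id`, `protein_id`, `sites`, `log2fc`,
#'   `p_value`, `regulated`.
#' @export
call_regulated <- function(phospho, design, config = run_config(),
                           contrast = NULL) {
  if (!isTRUE(attr(phospho, "phospho_normalized"))) {
    abort("call_regulated expects a normalize_phospho() table")
  }
  design <- validate_design(design)
  conds <- unique(design$condition)
  contrast <- contrast %||% conds
  if (length(contrast) != 2 || !all(contrast %in% conds)) {
    abort("contrast must name two design conditions")
  }
  ids_a <- condition_samples(design, contrast[1])
  ids_b <- condition_samples(design, contrast[2])
  if (length(ids_a) < 3 || length(ids_b) < 3) {
    abort("each condition needs >= 3 replicates")
  }
  a <- as.matrix(phospho[ids_a]); b <- as.matrix(phospho[ids_b])
  n1 <- ncol(a); n2 <- ncol(b)
  lfc <- rowMeans(b) - rowMeans(a)
  sp2 <- ((n1 - 1) * apply(a, 1, var) + (n2 - 1) * apply(b, 1, var)) /
    (n1 + n2 - 2)
  tstat <- lfc / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(tstat), df = n1 + n2 - 2)
  out <- tibble::tibble(
    peptide_id = phospho$peptide_id,
    protein_id = phospho$protein_id,
    sites = phospho$sites,
    log2fc = lfc,
    p_value = p,
    regulated = abs(lfc) > log2(config$phospho_fc_threshold) &
      p < config$phospho_p_threshold
  )
  attr(out, "contrast") <- contrast
  out
}

#' Residue distribution of phosphosites
#'
#' Site-level fractions of serine, threonine and tyrosine phosphosites;
#' multi-site peptides contribute each site once.
#'
#' @param phospho Wide phospho tibble.
#' @return A tibble `residue` (S, T, Y), `n_sites`, `fraction`
#'   (fractions sum to 1).
#' @export
residue_distribution <- function(phospho) {
  phospho <- validate_phospho(phospho)
  if (nrow(phospho) == 0) abort("phospho table is empty")
  sites <- phospho_sites_long(phospho)
  counts <- table(factor(sites$residue, levels = c("S", "T", "Y")))
  tibble::tibble(
    residue = names(counts),
    n_sites = as.integer(counts),
    fraction = as.integer(counts) / sum(counts)
  )
}
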