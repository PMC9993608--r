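#' @name ksea
#' @title Kinase-substrate enrichment analysis
#' @description Rank all quantified phosphopeptides by fold change and test
#'   whether each kinase's substrates concentrate at one extreme of the
#'   ranking, via the weighted Kolmogorov-Smirnov running-sum statistic
#'   (weight exponent 1). The null distribution permutes substrate-set
#'   membership over peptides (replicate counts are too small for sample
#'   permutation); the normalised enrichment score divides by the mean
#'   magnitude of same-sign null scores, so NES > 1 indicates positive
#'   enrichment in the shifted (diapause) condition.
NULL

# Enrichment score from sorted hit positions in a ranked list.
# absr: |ranking metric| in ranked order; hits step up by absr/sum(absr),
# misses step down by 1/(N - m). The signed maximum deviation is attained
# either just after a hit (maxima) or just before one (minima), so only
# those 2m points are evaluated. Ties in magnitude resolve positive.
ksea_es_positions <- function(pos, absr, N) {
  m <- length(pos)
  w <- absr[pos]
  nr <- sum(w)
  cw <- if (nr == 0) seq_len(m) / m else cumsum(w) / nr
  miss <- (pos - seq_len(m)) / (N - m)
  val_after <- cw - miss
  val_before <- c(0, cw[-m]) - miss
  hi <- max(val_after)
  lo <- min(val_before)
  # magnitude ties (which arise structurally from miss-count fractions)
  # resolve toward the positive extreme
  if (hi >= -lo - 1e-12) hi else lo
}

#' Kinase-substrate enrichment over a phosphopeptide ranking
#'
#' @param phospho Normalised phospho tibble ([normalize_phospho()]).
#' @param design Two-condition design (>= 3 replicates each).
#' @param map Kinase-substrate tibble (`kinase_id`, `protein_id`,
#'   `residue`, `position`), e.g. from [read_kinase_substrate_map()]. A
#'   peptide matches a kinase if any of its sites matches exactly
#'   (protein, residue, position); peptides may count in several kinases'
#'   sets.
#' @param config A [run_config()]; supplies `n_permutations`,
#'   `min_kinase_set_size` and `rng_seed`.
#' @param contrast Optional `c(reference, condition)`; the ranking metric is
#'   the per-peptide log2 fold change of `condition` over `reference`.
#' @param exact If `TRUE`, enumerate all substrate-label assignments instead
#'   of sampling (feasible only for small lists; capped at
#'   `choose(N, m) <= 2e5`).
#' @return A `ksea_result` tibble, one row per tested kinase:
#'   `kinase_id`, `n_substrate_peptides`, `es`, `nes`, `perm_p`, `fdr`,
#'   ordered by decreasing `nes`. Kinases with fewer matched peptides than
#'   `min_kinase_set_size`, or whose substrates cover the whole ranking,
#'   are excluded (attribute `excluded`).
#' @export
ksea <- function(phospho, design, map, config = run_config(),
                 contrast = NULL, exact = FALSE) {
  reg <- call_regulated(phospho, design, config, contrast)
  if (nrow(reg) == 0) abort("empty phosphopeptide ranking")
  # decreasing fold change; ties broken by peptide_id for determinism
  ord <- order(-reg$log2fc, reg$peptide_id)
  ranked <- reg[ord, ]
  absr <- abs(ranked$log2fc)
  N <- nrow(ranked)

  sites <- phospho_sites_long(phospho)
  matched <- dplyr::inner_join(
    sites, map, by = c("protein_id", "residue", "position"),
    relationship = "many-to-many"
  )
  hit_sets <- split(matched$peptide_id, matched$kinase_id)
  hit_sets <- lapply(hit_sets, function(p) {
    sort(unique(match(unique(p), ranked$peptide_id)))
  })

  all_kinases <- unique(map$kinase_id)
  unmatched <- setdiff(all_kinases, names(hit_sets))
  if (length(unmatched) > 0) {
    warn(paste0("kinase(s) with no matched peptides excluded: ",
                paste(unmatched, collapse = ", ")))
  }
  sizes <- lengths(hit_sets)
  too_small <- names(hit_sets)[sizes < config$min_kinase_set_size]
  full_cover <- names(hit_sets)[sizes == N]
  if (length(full_cover) > 0) {
    warn(paste0("kinase(s) whose substrates span the whole ranking ",
                "excluded: ", paste(full_cover, collapse = ", ")))
  }
  excluded <- tibble::tibble(
    kinase_id = c(unmatched, too_small, full_cover),
    reason = c(rep("no matched peptides", length(unmatched)),
               rep("fewer matched peptides than min_kinase_set_size",
                   length(too_small)),
               rep("substrates cover the whole ranking",
                   length(full_cover)))
  )
  tested <- setdiff(names(hit_sets), c(too_small, full_cover))

  res <- purrr::imap_dfr(hit_sets[tested], function(pos, kin) {
    m <- length(pos)
    es <- ksea_es_positions(pos, absr, N)
    k_idx <- match(kin, sort(tested))
    null_es <- if (exact && choose(N, m) <= 2e5) {
      apply(utils::combn(N, m), 2, ksea_es_positions, absr = absr, N = N)
    } else {
      with_seed(config$rng_seed + k_idx, {
        vapply(seq_len(config$n_permutations), function(i) {
          ksea_es_positions(sort(sample.int(N, m)), absr, N)
        }, 0)
      })
    }
    s <- sign(es)
    if (s == 0) {
      nes <- 0; p <- 1
    } else {
      same <- null_es[sign(null_es) == s]
      nes <- if (length(same) == 0) NA_real_ else es / mean(abs(same))
      # boundary equalities are structural (shared miss-count fractions),
      # so the comparison carries a small tolerance
      p <- (1 + sum(abs(same) >= abs(es) - 1e-9)) / (1 + length(same))
    }
    tibble::tibble(kinase_id = kin, n_substrate_peptides = m,
                   es = es, nes = nes, perm_p = p)
  })
  if (nrow(res) == 0) {
    res <- tibble::tibble(kinase_id = character(), n_substrate_peptides = integer(),
                          es = numeric(), nes = numeric(), perm_p = numeric(),
                          fdr = numeric())
  } else {
    res$fdr <- bh_fdr(res$perm_p)
    res <- dplyr::arrange(res, dplyr::desc(.data$nes))
  }
  attr(res, "excluded") <- excluded
  attr(res, "contrast") <- attr(reg, "contrast")
  class(res) <- c("ksea_result", class(res))
  res
}
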