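# tiny builders and independent oracles shared across the suite

toy_counts <- function(mat, gene_ids = sprintf("g%02d", seq_len(nrow(mat))),
                       sample_ids = colnames(mat)) {
  colnames(mat) <- sample_ids
  dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                   tibble::as_tibble(mat, .name_repair = "minimal"))
}

two_cond_design <- function(conditions = c("F0", "S1d"), n_replicates = 4) {
  diapause_design(conditions, n_replicates = n_replicates)
}

# expression tibble straight from a matrix of condition means replicated
expr_from_cond_means <- function(cm, design) {
  m <- cm[, design$condition, drop = FALSE]
  colnames(m) <- design$sample_id
  toy_counts(m, gene_ids = rownames(cm))
}

# --- independent GSEA/KSEA oracle -------------------------------------------
# plain running-sum walk over every position of the ranked list
oracle_es <- function(ranked_stats, hit, tol = 1e-9) {
  stopifnot(length(ranked_stats) == length(hit))
  n <- length(hit)
  nh <- sum(hit)
  nr <- sum(abs(ranked_stats[hit]))
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      run <- run + if (nr == 0) 1 / nh else abs(ranked_stats[i]) / nr
    } else {
      run <- run - 1 / (n - nh)
    }
    # magnitude ties (structural: pure miss-count fractions) go positive
    if (abs(run) > abs(best) + tol ||
        (abs(abs(run) - abs(best)) <= tol && run > best)) {
      best <- run
    }
  }
  best
}

# exhaustive enumeration of substrate-label assignments; same smoothed
# p definition as the package so agreement is exact
oracle_exact_p_nes <- function(ranked_stats, m, es_obs) {
  n <- length(ranked_stats)
  combs <- utils::combn(n, m)
  null_es <- apply(combs, 2, function(pos) {
    hit <- rep(FALSE, n); hit[pos] <- TRUE
    oracle_es(ranked_stats, hit)
  })
  s <- sign(es_obs)
  same <- null_es[sign(null_es) == s]
  list(
    p = (1 + sum(abs(same) >= abs(es_obs) - 1e-9)) / (1 + length(same)),
    nes = if (length(same) == 0) NA_real_ else es_obs / mean(abs(same))
  )
}

# build a small normalized-scale phospho experiment with one kinase whose
# substrates are the given peptide indices; log2 intensities chosen so the
# per-peptide fold changes equal `lfc` exactly (zero within-group variance
# would break the t-test, so tiny symmetric jitter keeps means exact)
small_ksea_instance <- function(lfc, hit_idx, seed = 1) {
  n <- length(lfc)
  design <- two_cond_design(n_replicates = 3)
  ids_a <- design$sample_id[design$condition == "F0"]
  ids_b <- design$sample_id[design$condition == "S1d"]
  jit <- c(-0.01, 0, 0.01)
  m <- matrix(0, n, 6)
  for (j in 1:3) m[, j] <- 10 + jit[j]
  for (j in 1:3) m[, 3 + j] <- 10 + lfc + jit[j]
  colnames(m) <- c(ids_a, ids_b)
  phospho <- dplyr::bind_cols(
    tibble::tibble(
      peptide_id = sprintf("p%02d", seq_len(n)),
      protein_id = sprintf("pr%02d", seq_len(n)),
      sites = paste0("S", seq_len(n))
    ),
    tibble::as_tibble(2^m, .name_repair = "minimal")
  )
  map <- tibble::tibble(
    kinase_id = "K1",
    protein_id = sprintf("pr%02d", hit_idx),
    residue = "S",
    position = hit_idx
  )
  list(phospho = phospho, design = design, map = map)
}
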