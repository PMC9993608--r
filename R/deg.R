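#' Median-of-ratios size factors
#'
#' Each sample's factor is the median, over genes with strictly positive
#' counts in every sample, of the ratio of its count to the gene's geometric
#' mean; factors are then rescaled to geometric mean 1. Ratios between
#' factors are exactly equivariant to rescaling a sample's counts.
#'
#' @param counts Wide count tibble (`gene_id` + sample columns).
#' @return Named numeric vector of per-sample size factors.
#' @export
#' @examples
#' cts <- tibble::tibble(gene_id = letters[1:4],
#'                       A = c(10, 20, 30, 40), B = c(20, 40, 60, 80))
#' size_factors(cts)
size_factors <- function(counts) {
  counts <- validate_counts(counts)
  m <- wide_to_matrix(counts, "gene_id")
  if (ncol(m) < 2) abort("size factors need >= 2 samples")
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    abort(paste0(
      "no gene has positive counts in every sample; size factors are ",
      "undefined (filter samples or supply deeper counts)"
    ))
  }
  lm_ <- log(m[all_pos, , drop = FALSE])
  log_gm <- rowMeans(lm_)
  lf <- apply(lm_ - log_gm, 2, median)
  f <- exp(lf - mean(lf))  # geometric mean 1
  setNames(f, colnames(m))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Validating wrapper around the standard step-up adjustment
#' (`stats::p.adjust(method = "BH")`).
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) {
    abort(sprintf("p-value out of [0, 1] at position %d",
                  which(!ok)[1]))
  }
  p.adjust(p_values, method = "BH")
}

# Fisher-scoring fit of a per-gene intercept (log link) for one condition:
# mu_i = sf_i * exp(beta), Var = mu + alpha mu^2 with per-gene alpha.
# Returns beta (natural log of the normalized group mean) and Fisher
# information; beta is floored so a half-count of normalized expression
# bounds fold changes for zero-count groups.
nb_group_fit <- function(y, sf, alpha, n_iter = 30) {
  stopifnot(nrow(y) == length(alpha), ncol(y) == length(sf))
  q0 <- pmax(rowSums(y) / sum(sf), 0.5)
  beta <- log(q0)
  floor_beta <- log(0.5)
  for (it in seq_len(n_iter)) {
    mu <- exp(beta) %o% sf
    denom <- 1 + alpha * mu
    score <- rowSums((y - mu) / denom)
    info <- rowSums(mu / denom)
    beta <- beta + score / pmax(info, 1e-12)
    beta <- pmin(pmax(beta, floor_beta), 30)
  }
  mu <- exp(beta) %o% sf
  info <- rowSums(mu / (1 + alpha * mu))
  list(beta = beta, info = info)
}

# Method-of-moments dispersion pooled over every design condition with
# replicates, shrunk 50/50 toward an a0 + a1/mu trend. For condition c,
# E[within-condition variance] = mu_c + alpha mu_c^2, so the df-weighted
# pooled variance satisfies E[v] = m1 + alpha m2 with m1/m2 the df-weighted
# first/second moments of the condition means.
estimate_dispersion <- function(norm_counts, condition) {
  conds <- unique(condition)
  ss <- 0; m1_num <- 0; m2_num <- 0; df_tot <- 0
  for (g in conds) {
    x <- norm_counts[, condition == g, drop = FALSE]
    n <- ncol(x)
    if (n < 2) next
    mu_c <- rowMeans(x)
    ss <- ss + apply(x, 1, var) * (n - 1)
    m1_num <- m1_num + (n - 1) * mu_c
    m2_num <- m2_num + (n - 1) * mu_c^2
    df_tot <- df_tot + (n - 1)
  }
  pooled_var <- ss / df_tot
  m1 <- m1_num / df_tot
  m2 <- m2_num / df_tot
  mom <- (pooled_var - m1) / m2
  mom_pos <- pmax(mom, 0)

  # trend alpha(mu) = a0 + a1/mu, trimmed least squares; fallback to median
  use <- is.finite(mom) & m1 > 0
  trend <- rep(median(mom_pos[use]), length(m1))
  if (sum(use) >= 10) {
    df <- data.frame(a = mom[use], x = 1 / m1[use])
    fit <- lm(a ~ x, data = df)
    res <- abs(fit$residuals)
    keep <- res <= 3 * (median(res) + 1e-12)
    if (sum(keep) >= 10) fit <- lm(a ~ x, data = df[keep, , drop = FALSE])
    co <- pmax(coef(fit), 0)
    trend <- co[1] + co[2] / m1
  }
  alpha <- 0.5 * mom_pos + 0.5 * trend
  attr(alpha, "df_resid") <- df_tot
  pmax(alpha, 1e-8)
}

#' Call differentially expressed genes for one contrast
#'
#' Self-contained negative-binomial Wald test on size-factor-normalised
#' counts: per-gene method-of-moments dispersion shrunk 50/50 toward an
#' `a0 + a1/mu` mean-dispersion trend, per-group mean fits by Fisher scoring,
#' and a Wald test of equal group means referred to the standard normal
#' distribution. The reported `log2fc` is
#' the pseudo-counted (0.5) ratio of normalised condition means, condition
#' `b` relative to reference `a`. Genes with zero counts in all samples of
#' both conditions, or failing the independent low-count filter (mean
#' normalised count < 1), are excluded from testing and from the FDR
#' denominator (`tested = FALSE`, call `ns`).
#'
#' @param counts Wide count tibble.
#' @param design Sample design.
#' @param contrast Character pair `c(reference, condition)`.
#' @param config A [run_config()]; supplies `fdr_threshold` and
#'   `lfc_threshold` for the up/down/ns calls.
#' @return A tibble (one row per input gene): `gene_id`, `base_mean`,
#'   `log2fc`, `p_value`, `fdr`, `call`, `tested`, with attribute
#'   `contrast`. `call` is `up` iff `fdr < fdr_threshold` and
#'   `log2fc > lfc_threshold`; `down` mirrors; otherwise `ns`.
#' @export
call_degs <- function(counts, design, contrast, config = run_config()) {
  stopifnot(length(contrast) == 2)
  design <- validate_design(design)
  counts <- validate_counts(counts)
  ids_a <- condition_samples(design, contrast[1])
  ids_b <- condition_samples(design, contrast[2])
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    abort("both contrast conditions need >= 2 replicates")
  }
  # size factors and dispersion use the full design: every condition with
  # replicates informs the mean-dispersion relationship
  m_all <- wide_to_matrix(counts[c("gene_id", design$sample_id)], "gene_id")
  sf_all <- size_factors(counts[c("gene_id", design$sample_id)])
  norm_all <- sweep(m_all, 2, sf_all, "/")

  m <- m_all[, c(ids_a, ids_b), drop = FALSE]
  sf <- sf_all[c(ids_a, ids_b)]
  norm <- norm_all[, c(ids_a, ids_b), drop = FALSE]
  group <- rep(c("a", "b"), c(length(ids_a), length(ids_b)))

  nonzero <- rowSums(m) > 0
  mu_bar <- rowMeans(norm)
  tested <- nonzero & mu_bar >= 1

  out <- tibble::tibble(
    gene_id = rownames(m),
    base_mean = mu_bar,
    log2fc = NA_real_,
    p_value = NA_real_,
    fdr = NA_real_,
    call = "ns",
    tested = tested
  )

  if (any(tested)) {
    yt <- m[tested, , drop = FALSE]
    alpha <- estimate_dispersion(
      norm_all[tested, , drop = FALSE],
      design$condition[match(colnames(norm_all), design$sample_id)]
    )
    fit_a <- nb_group_fit(yt[, group == "a", drop = FALSE],
                          sf[group == "a"], alpha)
    fit_b <- nb_group_fit(yt[, group == "b", drop = FALSE],
                          sf[group == "b"], alpha)
    se_ln <- sqrt(1 / fit_a$info + 1 / fit_b$info)
    z <- (fit_b$beta - fit_a$beta) / se_ln
    # moderated reference: t with the dispersion-estimation df (pooled
    # within-condition residual df plus an equal contribution from the
    # 50/50 trend shrinkage)
    df_disp <- attr(alpha, "df_resid")
    p <- 2 * pt(-abs(z), df = 2 * df_disp)
    mean_a <- rowMeans(norm[tested, group == "a", drop = FALSE])
    mean_b <- rowMeans(norm[tested, group == "b", drop = FALSE])
    lfc <- log2(mean_b + 0.5) - log2(mean_a + 0.5)
    out$log2fc[tested] <- lfc
    out$p_value[tested] <- p
    out$fdr[tested] <- bh_fdr(p)
  }

  out$call <- deg_call(out$log2fc, out$fdr, config)
  attr(out, "contrast") <- contrast
  class(out) <- c("deg_table", class(out))
  out
}

# pure function of (log2fc, fdr, thresholds)
deg_call <- function(log2fc, fdr, config = run_config()) {
  call <- rep("ns", length(log2fc))
  sig <- !is.na(fdr) & fdr < config$fdr_threshold
  call[sig & log2fc > config$lfc_threshold] <- "up"
  call[sig & log2fc < -config$lfc_threshold] <- "down"
  call
}

deg_genes <- function(deg_table) {
  deg_table$gene_id[deg_table$call != "ns"]
}
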