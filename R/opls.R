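#' Fit a two-class OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis:
#' variables are mean-centred and unit-variance scaled, the class response
#' is coded +/-1 and centred, variation orthogonal to the response is
#' removed component by component, and a single predictive component is
#' fitted on the filtered matrix. VIP scores are computed on the predictive
#' component, so `sum(vip^2)` equals the number of variables.
#'
#' @param matrix Wide metabolite tibble (`metabolite_id` + sample columns).
#' @param groups Tibble `sample_id`, `group` with exactly two groups of
#'   >= 3 samples each.
#' @param n_orthogonal Orthogonal components to remove. Default 1.
#' @param scaling `"uv"` (unit variance, default), `"pareto"` or `"none"`;
#'   variables are always mean-centred.
#' @return An object of class `oplsda`: predictive scores `t_pred`,
#'   weights `w`, loadings `p`, orthogonal scores/loadings
#'   (`t_orth`, `p_orth`, `w_orth`), `vip`, `r2x`, `r2y`, scaling
#'   parameters, variable and sample ids. Has [tidy()]/[glance()] methods.
#' @export
fit_oplsda <- function(matrix, groups, n_orthogonal = 1,
                       scaling = c("uv", "pareto", "none")) {
  scaling <- match.arg(scaling)
  groups <- tibble::as_tibble(groups)
  if (!all(c("sample_id", "group") %in% names(groups))) {
    abort("groups needs columns sample_id and group")
  }
  lv <- unique(groups$group)
  if (length(lv) != 2) abort("OPLS-DA requires exactly two groups")
  if (any(table(groups$group) < 3)) abort("each group needs >= 3 samples")
  m <- wide_to_matrix(tibble::as_tibble(matrix), names(matrix)[1])
  missing <- setdiff(groups$sample_id, colnames(m))
  if (length(missing) > 0) {
    abort(paste0("matrix missing sample(s): ", paste(missing, collapse = ", ")))
  }
  x <- t(m[, groups$sample_id, drop = FALSE])  # samples x variables

  vars_sd <- apply(x, 2, sd)
  zero_var <- vars_sd == 0
  if (any(zero_var)) {
    warn(paste0("removing zero-variance variable(s): ",
                paste(colnames(x)[zero_var], collapse = ", ")))
    x <- x[, !zero_var, drop = FALSE]
    vars_sd <- vars_sd[!zero_var]
  }
  if (ncol(x) < 2) abort("fewer than 2 variables after filtering")

  mu <- colMeans(x)
  scale_div <- switch(scaling, uv = vars_sd, pareto = sqrt(vars_sd),
                      none = rep(1, ncol(x)))
  xs <- sweep(sweep(x, 2, mu, "-"), 2, scale_div, "/")
  y <- ifelse(groups$group == lv[1], 1, -1)
  y <- y - mean(y)
  ssx_total <- sum(xs^2)

  # orthogonal filtering (one NIPALS pass per component; single-y w is exact)
  t_orth <- matrix(0, nrow(xs), 0); p_orth <- matrix(0, ncol(xs), 0)
  w_orth <- matrix(0, ncol(xs), 0)
  xf <- xs
  for (k in seq_len(n_orthogonal)) {
    w <- drop(crossprod(xf, y)) / sum(y^2)
    w <- w / sqrt(sum(w^2))
    tt <- drop(xf %*% w)
    p <- drop(crossprod(xf, tt)) / sum(tt^2)
    wo <- p - sum(w * p) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10) break  # no orthogonal variation left
    wo <- wo / nwo
    to <- drop(xf %*% wo)
    po <- drop(crossprod(xf, to)) / sum(to^2)
    xf <- xf - tcrossprod(to, po)
    t_orth <- cbind(t_orth, to); p_orth <- cbind(p_orth, po)
    w_orth <- cbind(w_orth, wo)
  }

  # predictive component on the filtered matrix
  w <- drop(crossprod(xf, y)) / sum(y^2)
  w <- w / sqrt(sum(w^2))
  t_pred <- drop(xf %*% w)
  p <- drop(crossprod(xf, t_pred)) / sum(t_pred^2)
  q <- sum(y * t_pred) / sum(t_pred^2)
  r2y <- 1 - sum((y - q * t_pred)^2) / sum(y^2)
  r2x <- sum(t_pred^2) * sum(p^2) / ssx_total

  # single predictive component: VIP_j = sqrt(p_vars) * |w_j| / ||w||
  vip <- sqrt(ncol(xf)) * abs(w) / sqrt(sum(w^2))

  structure(
    list(
      variable_ids = colnames(xs), sample_ids = groups$sample_id,
      group_levels = lv, y = y,
      w = setNames(w, colnames(xs)), p = setNames(p, colnames(xs)),
      q = q, t_pred = setNames(t_pred, groups$sample_id),
      t_orth = t_orth, p_orth = p_orth, w_orth = w_orth,
      vip = setNames(vip, colnames(xs)),
      r2x = r2x, r2y = r2y,
      center = mu, scale = scale_div, scaling = scaling,
      n_orthogonal = ncol(t_orth)
    ),
    class = "oplsda"
  )
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf(
    "<oplsda> %d variables, %d samples (%s vs %s); 1 predictive + %d orthogonal; R2X = %.3f, R2Y = %.3f\n",
    length(x$variable_ids), length(x$sample_ids),
    x$group_levels[1], x$group_levels[2], x$n_orthogonal, x$r2x, x$r2y
  ))
  invisible(x)
}

#' Variable importance in projection
#'
#' VIP on the single predictive component of a fitted [fit_oplsda()] model;
#' `sum(vip^2)` equals the number of variables.
#'
#' @param model A fitted `oplsda`.
#' @return Named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "oplsda")) abort("vip_scores expects a fitted oplsda")
  model$vip
}

#' @export
tidy.oplsda <- function(x, ...) {
  tibble::tibble(
    metabolite_id = x$variable_ids,
    weight = unname(x$w),
    loading = unname(x$p),
    vip = unname(x$vip)
  )
}

#' @export
glance.oplsda <- function(x, ...) {
  tibble::tibble(
    n_variables = length(x$variable_ids),
    n_samples = length(x$sample_ids),
    n_orthogonal = x$n_orthogonal,
    r2x = x$r2x, r2y = x$r2y
  )
}

#' Screen metabolites by VIP and Student's t-test
#'
#' The joint rule used on targeted TCA/glycolysis panels: a metabolite is
#' selected iff its OPLS-DA VIP exceeds `config$vip_threshold` and its
#' two-sided pooled-variance t-test p-value is below 0.05. The two-tier
#' outcome is reported so VIP-positive but t-test-negative metabolites
#' (`vip_only`) remain visible.
#'
#' @param matrix Wide metabolite tibble.
#' @param groups Tibble `sample_id`, `group` (two groups, >= 3 each).
#' @param config A [run_config()].
#' @param n_orthogonal Passed to [fit_oplsda()].
#' @param p_threshold t-test threshold. Default 0.05.
#' @return A tibble: `metabolite_id`, `vip`, `t_p`, `selected`, `vip_only`,
#'   with the fitted model in attribute `model`.
#' @export
screen_metabolites <- function(matrix, groups, config = run_config(),
                               n_orthogonal = 1, p_threshold = 0.05) {
  model <- fit_oplsda(matrix, groups, n_orthogonal = n_orthogonal)
  m <- wide_to_matrix(tibble::as_tibble(matrix), names(matrix)[1])
  ids_a <- groups$sample_id[groups$group == model$group_levels[1]]
  ids_b <- groups$sample_id[groups$group == model$group_levels[2]]
  tp <- vapply(model$variable_ids, function(met) {
    t.test(m[met, ids_a], m[met, ids_b], var.equal = TRUE)$p.value
  }, 0)
  out <- tibble::tibble(
    metabolite_id = model$variable_ids,
    vip = unname(model$vip),
    t_p = unname(tp),
    selected = vip > config$vip_threshold & t_p < p_threshold,
    vip_only = vip > config$vip_threshold & t_p >= p_threshold
  )
  attr(out, "model") <- model
  class(out) <- c("metabolite_screen", class(out))
  out
}
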