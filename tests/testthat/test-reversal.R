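test_that("reversal regression recovers exact geometric anchors", {
  des <- diapause_design(c("F0", "S1d", "S2d", "In4h"), n_replicates = 2)
  # build condition means so that y == x exactly: In4h mean equals F0 mean
  set.seed(1)
  f0 <- exp(rnorm(40, 3, 1))
  s2 <- exp(rnorm(40, 3, 1))
  cm <- cbind(F0 = f0, S1d = s2, S2d = s2, In4h = f0)
  rownames(cm) <- sprintf("g%02d", 1:40)
  expr <- expr_from_cond_means(cm, des)
  fit <- reversal_fit(rownames(cm), expr, des, "In4h")
  expect_equal(fit$slope, 1, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-10)

  # no recovery: In4h means equal S2d means -> y == 0, slope 0
  cm0 <- cm; cm0[, "In4h"] <- cm0[, "S2d"]
  fit0 <- reversal_fit(rownames(cm0), expr_from_cond_means(cm0, des), des,
                       "In4h")
  expect_equal(fit0$slope, 0, tolerance = 1e-10)

  # invariance to uniform rescaling of all expression values
  fit_scaled <- reversal_fit(
    rownames(cm), expr_from_cond_means(cm, des), des, "In4h",
    pseudo_count = 0
  )
  fit_scaled2 <- reversal_fit(
    rownames(cm), expr_from_cond_means(cm * 10, des), des, "In4h",
    pseudo_count = 0
  )
  expect_equal(fit_scaled$slope, fit_scaled2$slope, tolerance = 1e-10)
  expect_equal(fit_scaled$pearson_r, fit_scaled2$pearson_r,
               tolerance = 1e-10)

  # gene-order invariance
  shuffled <- expr[rev(seq_len(nrow(expr))), ]
  fit_r <- reversal_fit(rownames(cm), shuffled, des, "In4h")
  expect_equal(fit$slope, fit_r$slope)

  expect_error(reversal_fit(character(0), expr, des, "In4h"), "empty")
  expect_error(reversal_fit(c("g01", "g02"), expr, des, "In4h"), "fewer than 3")
})

test_that("planted reversal slopes are recovered across the schedule", {
  des <- diapause_design(c("F0", "S1d", "S2d", "In1h", "In2h", "In4h"))
  sched <- c("In1h" = 0.2, "In2h" = 0.45, "In4h" = 0.79)
  hits <- sapply(1:20, function(s) {
    sim <- simulate_counts(
      sim_spec(n_genes = 280, gene_class_fractions = c(reversal = 1),
               slope_schedule = sched, rng_seed = s), des
    )
    expr <- compute_expression(sim$counts, unit = "CPM")
    deg <- call_degs(sim$counts, des, c("F0", "S2d"))
    degset <- deg$gene_id[deg$call != "ns"]
    sl <- vapply(names(sched), function(ic) {
      reversal_fit(degset, expr, des, ic)$slope
    }, 0)
    all(abs(sl - sched) <= 0.1)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("slope trajectory orders fits and flags monotonicity", {
  mk <- function(cond, slope) {
    structure(list(incubation_condition = cond, slope = slope),
              class = "reversal_fit")
  }
  tr <- slope_trajectory(list(mk("In4h", 0.79), mk("In1h", 0.2),
                              mk("In2h", 0.45)))
  expect_equal(tr$condition, c("In1h", "In2h", "In4h"))
  expect_equal(tr$slope, c(0.2, 0.45, 0.79))
  expect_true(attr(tr, "monotone"))
  tr2 <- slope_trajectory(list(mk("In1h", 0.5), mk("In2h", 0.3)))
  expect_false(attr(tr2, "monotone"))
  expect_error(slope_trajectory(list(mk("In1h", 0.5))), ">= 2")
})

test_that("gene-set fold-change summaries hit closed forms and determinism", {
  des <- diapause_design(c("F0", "S2d"), n_replicates = 2)
  # 5 set genes with fold change exactly 10 (S2d over F0); 200 background
  n_bg <- 200
  cm <- rbind(
    matrix(rep(c(3, 30), each = 5), 5, 2),
    matrix(rep(c(7, 7), each = n_bg), n_bg, 2)
  )
  colnames(cm) <- c("F0", "S2d")
  rownames(cm) <- c(sprintf("set%d", 1:5), sprintf("bg%03d", seq_len(n_bg)))
  expr <- expr_from_cond_means(cm, des)
  ann <- tibble::tibble(term_id = "t", term_name = "t",
                        gene_id = sprintf("set%d", 1:5))
  cfg <- run_config(rng_seed = 5, control_set_size = 150)
  s <- gene_set_fc_summary(ann, expr, des, list(c("F0", "S2d")), cfg,
                           pseudo_count = 0)
  expect_equal(s$median_log10fc, 1)
  expect_equal(s$n_control, 150)
  expect_equal(s$control_median, 0)

  # control sampling deterministic under the configured seed
  s2 <- gene_set_fc_summary(ann, expr, des, list(c("F0", "S2d")), cfg,
                            pseudo_count = 0)
  expect_identical(s, s2)

  expect_error(
    gene_set_fc_summary(
      tibble::tibble(term_id = "t", term_name = "t", gene_id = "nope"),
      expr, des, list(c("F0", "S2d")), cfg
    ),
    "fewer than 3"
  )
})

test_that("control summaries are centred under a null simulation", {
  des <- diapause_design(c("F0", "S1d", "S2d"), n_replicates = 3)
  sim <- simulate_counts(
    sim_spec(n_genes = 2000, gene_class_fractions = c(null = 1),
             rng_seed = 9), des
  )
  expr <- compute_expression(sim$counts, unit = "CPM")
  ann <- tibble::tibble(term_id = "t", term_name = "t",
                        gene_id = sim$counts$gene_id[1:20])
  s <- gene_set_fc_summary(ann, expr, des,
                           list(c("F0", "S1d"), c("F0", "S2d")),
                           run_config(rng_seed = 1))
  expect_true(all(abs(s$control_median) < 0.05))
})
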