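# condition-mean fixture covering the whole course
marker_cm <- function(...) {
  rows <- list(...)
  cm <- do.call(rbind, rows)
  colnames(cm) <- c("F0", "S1d", "S2d", "S4d", "S8d", "S12d",
                    "In0.5h", "In1h", "In2h", "In4h")
  rownames(cm) <- names(rows)
  cm
}

test_that("marker filter conditions (i)-(iii) behave on constructed genes", {
  des <- diapause_design(c("F0", "S1d", "S2d", "S4d", "S8d", "S12d",
                           "In0.5h", "In1h", "In2h", "In4h"),
                         n_replicates = 2)
  cm <- marker_cm(
    # clean up-marker: high in all storage, decays below S2d, back at F0
    good_up   = c(10, 42, 40, 41, 44, 40, 30, 20, 12, 10),
    # clean down-marker (mirrored)
    good_down = c(40, 11, 10, 10, 9, 10, 15, 22, 33, 40),
    # constant gene: strict inequality of (i) fails
    flat      = rep(20, 10),
    # violates (iii): still 4-fold above F0 at In4h
    stuck     = c(10, 42, 40, 41, 44, 40, 40, 40, 40, 40),
    # violates (ii): overshoots S2d during incubation
    overshoot = c(10, 42, 40, 41, 44, 40, 70, 20, 12, 10)
  )
  expr <- expr_from_cond_means(cm, des)
  rep_ <- screen_markers(rownames(cm), expr, des, NULL,
                         run_config(rng_seed = 1))
  dir <- setNames(rep_$direction, rep_$gene_id)
  expect_equal(unname(dir["good_up"]), "up_candidate")
  expect_equal(unname(dir["good_down"]), "down_candidate")
  expect_equal(unname(dir["flat"]), "fail")
  expect_equal(unname(dir["stuck"]), "fail")
  expect_false(rep_$cond_iii_pass[rep_$gene_id == "stuck"])
  expect_equal(unname(dir["overshoot"]), "fail")
  expect_false(rep_$cond_ii_pass[rep_$gene_id == "overshoot"])

  # absent candidate is a recorded failure, not an error
  rep2 <- screen_markers("ghost", expr, des, NULL, run_config(rng_seed = 1))
  expect_equal(rep2$direction, "fail")
  expect_match(rep2$reason, "absent")

  # a DEG in In4h-vs-F0 fails condition (iii) even inside the tolerance
  deg_fake <- tibble::tibble(gene_id = "good_up", call = "up")
  attr(deg_fake, "contrast") <- c("F0", "In4h")
  rep3 <- screen_markers("good_up", expr, des, deg_fake,
                         run_config(rng_seed = 1))
  expect_equal(rep3$direction, "fail")
})

test_that("raising the similarity tolerance never turns a pass into a fail", {
  des <- diapause_design(c("F0", "S1d", "S2d", "S4d", "S8d", "S12d",
                           "In0.5h", "In1h", "In2h", "In4h"))
  sim <- simulate_counts(
    sim_spec(n_genes = 300, gene_class_fractions = c(
      null = 0.8, marker_up = 0.1, marker_down = 0.1
    ), base_mean = 1000, dispersion = 0.03, rng_seed = 6), des
  )
  expr <- compute_expression(sim$counts, unit = "normalized")
  cand <- sim$counts$gene_id[1:150]
  for (tol in list(c(0.5, 1), c(1, 2))) {
    lo <- screen_markers(cand, expr, des, NULL,
                         run_config(rng_seed = 1,
                                    similarity_tolerance = tol[1]))
    hi <- screen_markers(cand, expr, des, NULL,
                         run_config(rng_seed = 1,
                                    similarity_tolerance = tol[2]))
    passed_lo <- lo$gene_id[lo$direction != "fail"]
    passed_hi <- hi$gene_id[hi$direction != "fail"]
    expect_true(all(passed_lo %in% passed_hi))
  }
})

test_that("planted markers are recovered from the simulation truth table", {
  des <- diapause_design()
  sim <- simulate_counts(
    sim_spec(n_genes = 400, gene_class_fractions = c(
      null = 0.7, up_diapause = 0.12, down_diapause = 0.12,
      marker_up = 0.03, marker_down = 0.03
    ), base_mean = 1000, dispersion = 0.03, rng_seed = 8), des
  )
  expr <- compute_expression(sim$counts, unit = "normalized")
  deg_s1d <- call_degs(sim$counts, des, c("F0", "S1d"))
  cand <- deg_s1d$gene_id[deg_s1d$call != "ns"]
  deg_in4h <- call_degs(sim$counts, des, c("F0", "In4h"))
  rep_ <- screen_markers(cand, expr, des, deg_in4h)
  called <- rep_$gene_id[rep_$direction != "fail"]
  planted <- sim$truth$gene_id[sim$truth$class %in%
                                 c("marker_up", "marker_down")]
  expect_setequal(called, planted)
  # direction agrees with the planted class
  up_called <- rep_$gene_id[rep_$direction == "up_candidate"]
  expect_true(all(sim$truth$class[match(up_called, sim$truth$gene_id)] ==
                    "marker_up"))
})

test_that("proliferation tally counts intersections and flags direction", {
  deg <- tibble::tibble(gene_id = c("A", "B", "C"),
                        call = c("up", "up", "down"))
  neg <- tibble::tibble(term_id = "n", term_name = "negative regulation",
                        gene_id = c("A", "B"))
  pos <- tibble::tibble(term_id = "p", term_name = "positive regulation",
                        gene_id = "C")
  t1 <- proliferation_tally(deg, neg, pos)
  expect_equal(
    unlist(t1[c("up_negative", "up_positive", "down_negative",
                "down_positive")]),
    c(up_negative = 2, up_positive = 0, down_negative = 0,
      down_positive = 1)
  )
  expect_true(t1$direction_consistent)

  empty <- tibble::tibble(gene_id = character(0), call = character(0))
  t0 <- proliferation_tally(empty, neg, pos)
  expect_equal(t0$up_negative + t0$down_positive +
                 t0$up_positive + t0$down_negative, 0)
})

test_that("biased up-DEG sampling from the negative set flips the flag", {
  neg_genes <- sprintf("n%03d", 1:100)
  pos_genes <- sprintf("p%03d", 1:100)
  neg <- tibble::tibble(term_id = "n", term_name = "n", gene_id = neg_genes)
  pos <- tibble::tibble(term_id = "p", term_name = "p", gene_id = pos_genes)
  flags <- vapply(1:20, function(s) {
    set.seed(s)
    # up-DEGs drawn from the negative set at odds 3:1, down-DEGs reversed
    up <- c(sample(neg_genes, 30), sample(pos_genes, 10))
    down <- c(sample(neg_genes, 10), sample(pos_genes, 30))
    deg <- tibble::tibble(gene_id = c(up, down),
                          call = rep(c("up", "down"), each = 40))
    proliferation_tally(deg, neg, pos)$direction_consistent
  }, TRUE)
  expect_gte(mean(flags), 0.95)
})

test_that("ddct matches closed forms and is shift-invariant", {
  expect_equal(ddct(25, 20, 24, 20)$relative_expression, 0.5)
  expect_equal(ddct(22, 20, 25, 20)$relative_expression, 8)
  expect_equal(ddct(21, 21, 21, 21)$relative_expression, 1)
  base <- ddct(25, 20, 24, 20)
  shifted <- ddct(28, 23, 27, 23)
  expect_equal(base$relative_expression, shifted$relative_expression)
  expect_error(ddct(46, 20, 24, 20), "\\(0, 45\\)")
  expect_error(ddct(25, 20, -1, 20), "\\(0, 45\\)")
})
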