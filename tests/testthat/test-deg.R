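test_that("size factors follow median-of-ratios on worked instances", {
  # identical columns -> (1, 1)
  ident <- toy_counts(matrix(c(5, 9, 13, 5, 9, 13), 3, 2),
                      sample_ids = c("A", "B"))
  expect_equal(unname(size_factors(ident)), c(1, 1))

  # B = 2A exactly -> factors proportional to (1, 2), geometric mean 1
  prop <- toy_counts(matrix(c(10, 20, 30, 40, 20, 40, 60, 80), 4, 2),
                     sample_ids = c("A", "B"))
  f <- size_factors(prop)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(f["B"] / f["A"]), 2)

  # ratio equivariance: scaling one sample by c scales its factor ratio by c
  scaled <- prop
  scaled$B <- scaled$B * 3
  f2 <- size_factors(scaled)
  expect_equal(unname(f2["B"] / f2["A"]), 3 * unname(f["B"] / f["A"]))

  # no gene positive everywhere is fatal
  holes <- toy_counts(matrix(c(0, 5, 5, 0), 2, 2), sample_ids = c("A", "B"))
  expect_error(size_factors(holes), "no gene")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  des <- diapause_design(c("F0", "S1d", "S2d"), n_replicates = 2)
  sim <- simulate_counts(sim_spec(n_genes = 300, rng_seed = 21), des)
  m <- as.matrix(sim$counts[-1])
  ours <- size_factors(sim$counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  # both defined up to a common scale; compare after geometric-mean scaling
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("bh_fdr reproduces the hand-computed step-up adjustment", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.9)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.1, 1.2)), "position 2")
})

test_that("DEG calls obey thresholds and degenerate inputs", {
  des <- diapause_design(c("F0", "S1d", "S2d"), n_replicates = 3)
  sim <- simulate_counts(
    sim_spec(n_genes = 500, gene_class_fractions = c(
      null = 0.8, up_diapause = 0.1, down_diapause = 0.1
    ), rng_seed = 2), des
  )
  cts <- sim$counts
  # a gene with identical counts in every sample is ns with log2fc 0
  flat <- which(sim$truth$class == "null")[1]
  cts[flat, -1] <- as.list(rep(50, nrow(des)))
  deg <- call_degs(cts, des, c("F0", "S2d"),
                   run_config(rng_seed = 1))
  expect_equal(deg$call[flat], "ns")
  expect_lt(abs(deg$log2fc[flat]), 0.3)  # size-factor jitter only

  # calls are a pure function of the stored columns
  cfg <- run_config(rng_seed = 1)
  rederived <- ifelse(
    !is.na(deg$fdr) & deg$fdr < cfg$fdr_threshold & deg$log2fc > cfg$lfc_threshold, "up",
    ifelse(!is.na(deg$fdr) & deg$fdr < cfg$fdr_threshold &
             deg$log2fc < -cfg$lfc_threshold, "down", "ns")
  )
  expect_identical(deg$call, rederived)

  # untested genes are excluded from the FDR denominator
  expect_true(all(is.na(deg$fdr[!deg$tested])))
  expect_equal(
    deg$fdr[deg$tested],
    bh_fdr(deg$p_value[deg$tested])
  )

  # preconditions
  expect_error(call_degs(cts, des, c("F0", "In4h")), "absent")
  des1 <- des[des$replicate == 1 | des$condition != "F0", ]
  expect_error(call_degs(cts[c("gene_id", des1$sample_id)], des1,
                         c("F0", "S2d")), "replicates")
})

test_that("planted effects are detected with high power", {
  des <- diapause_design(c("F0", "S1d", "S2d", "S4d", "S8d", "S12d"))
  sim <- simulate_counts(
    sim_spec(n_genes = 1000, base_mean = 100, base_mean_sdlog = 0,
             effect_lfc = 2, rng_seed = 31), des
  )
  deg <- call_degs(sim$counts, des, c("F0", "S2d"))
  true_de <- sim$truth$class %in%
    c("up_diapause", "down_diapause", "marker_up", "marker_down")
  expect_gte(mean(deg$call[true_de] != "ns"), 0.9)
  # directions match the plants among called genes
  up_called <- deg$call == "up" & true_de
  expect_true(all(sim$truth$planted_lfc[up_called] > 0))
})

test_that("DEG direction agrees with DESeq2 on a shared fixture", {
  des <- diapause_design(c("F0", "S1d", "S2d"), n_replicates = 3)
  sim <- simulate_counts(
    sim_spec(n_genes = 400, gene_class_fractions = c(
      null = 0.7, up_diapause = 0.15, down_diapause = 0.15
    ), base_mean = 200, rng_seed = 13), des
  )
  deg <- call_degs(sim$counts, des, c("F0", "S2d"))
  m <- as.matrix(sim$counts[-1])
  coldata <- data.frame(condition = factor(des$condition,
                                           levels = c("F0", "S1d", "S2d")))
  dds <- suppressMessages(DESeq2::DESeq(
    DESeq2::DESeqDataSetFromMatrix(m, coldata, ~condition), quiet = TRUE
  ))
  ref <- DESeq2::results(dds, contrast = c("condition", "S2d", "F0"))
  both <- deg$tested & !is.na(ref$padj)
  sig_both <- both & deg$call != "ns" & ref$padj < 0.01
  # every gene both pipelines call at FDR 0.01 moves the same way
  expect_true(all(sign(deg$log2fc[sig_both]) ==
                    sign(ref$log2FoldChange[sig_both])))
  # call overlap is substantial (no numeric parity claimed)
  ours <- deg$call != "ns"
  theirs <- !is.na(ref$padj) & ref$padj < 0.01 &
    abs(ref$log2FoldChange) > 1
  expect_gt(sum(ours & theirs) / max(sum(ours | theirs), 1), 0.7)
})
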