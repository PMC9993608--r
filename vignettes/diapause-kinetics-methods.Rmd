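---
title: "Methods: locating diapause termination in multi-omic time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locating diapause termination in multi-omic time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diapausekit)
```

## The biological setting

Freshly oviposited chicken eggs hold a blastoderm of roughly 25 hours of
development. Storage below physiological zero (about 21 °C) arrests the
embryo in a reversible diapause; returning the egg to 37.8 °C restarts
development. diapausekit implements the statistical machinery for asking
*when* that restart happens and *which* molecules track it, across three
data layers: bulk RNA-seq counts along a storage series (`F0`, then
`S1d`–`S12d`, time in days) and an incubation series (`S2d` then
`In0.5h`–`In12h`, time in hours), TMT phosphopeptide intensities, and a
targeted metabolite panel.

All user-facing functions take tabular data (tibbles) and return tibbles or
small fitted objects with `tidy()`/`glance()`/`autoplot()` methods, so the
pipeline composes with ordinary tidyverse code.

## Differential expression along the time course

`call_degs()` is a self-contained negative-binomial Wald caller:

* **Normalisation.** Median-of-ratios size factors (`size_factors()`),
  rescaled to geometric mean one. Factor *ratios* are exactly equivariant to
  rescaling any one sample's counts.
* **Dispersion.** A single NB2 parameterisation, `Var = mu + alpha mu^2`.
  The method-of-moments estimate pools the within-condition variance over
  *every* design condition with replicates, not only the two contrast
  groups — at three replicates per condition the contrast-only estimate is
  far too noisy to test with. The per-gene estimate is then shrunk 50/50
  toward an `a0 + a1/mu` trend fitted by trimmed least squares.
* **Testing.** Per-group means are fitted by Fisher scoring on the log
  scale with size factors as exposures; the Wald statistic for equal means
  is referred to a t distribution with twice the pooled residual degrees of
  freedom, treating the trend shrinkage as an equal prior contribution.
  This moderation is what makes the caller simultaneously calibrated (null
  false-positive rate near nominal) and powerful at three-versus-three
  replicates; a plain normal reference is slightly liberal and a
  contrast-only residual-df t is hopelessly conservative.
* **Reporting.** `log2fc` is the pseudo-counted (0.5) ratio of normalised
  condition means, so zero-count groups give bounded fold changes. Genes
  with zero counts across both conditions or mean normalised count below 1
  are excluded from testing and from the Benjamini–Hochberg denominator.
  Calls use the study thresholds FDR < 0.01 and |log2FC| > 1 and are a pure
  function of the stored columns.

No numerical parity with any DESeq release is claimed; a test checks
directional agreement and substantial call overlap with DESeq2 on a shared
fixture, and that the size factors coincide with DESeq2's
median-of-ratios implementation.

### Interval-normalised rates and the transition window

Figure-style summaries divide DEG counts by elapsed time. Because "number
of interval days/hours" can be read as elapsed-since-reference or
gap-to-previous, `rate_series()` emits both: `rate_cumulative`
(count / elapsed time) and `rate_incremental` (count change / time gap).
`transition_window()` works on the incremental variant and returns the
consecutive pair of time points with the largest positive *acceleration*
of expression turnover, breaking ties toward the earlier pair — the
operational definition of "when the embryo wakes up". With fewer than three
time points the question is ill-posed and the function errors; a monotone
or flat series returns a sentinel with a warning.

`retention_fraction()` quantifies the coherence of a DEG trajectory: the
fraction of each time point's called genes that are called again at the
next time point. Under planted monotone diapause effects, retention stays
above 0.8 at every step, matching the qualitative behaviour expected of a
gradual, non-switch-like transition.

## Reversal regression

For a DEG set identified from the diapause contrast (F0 vs S2d),
`reversal_fit()` regresses, gene by gene,
`y = log2(mean_In / mean_S2d)` on `x = log2(mean_F0 / mean_S2d)`
(condition-mean expression, pseudo-count 0.5). The sign convention fixes
the x-axis as pre-diapause relative to diapause, so a slope of 0 means
expression is still at the diapause level and a slope of 1 means full
return to the pre-diapause state. Ordinary least squares of y on x is used
(one regression line per panel, with Pearson R and its two-sided zero-
correlation p), not orthogonal regression. Fold changes come from
condition-mean expression rather than the DEG caller's model estimates,
keeping the regression independent of test internals.

`gene_set_fc_summary()` summarises per-gene log10 fold changes over an
annotated set against a control of 150 genes (configurable) sampled
uniformly without replacement from the expressed genes outside the set,
seeded by `run_config(rng_seed = )` so the control is reproducible.

## Marker screen

`screen_markers()` encodes the three-condition temperature-responsiveness
filter on condition means. For an up-marker: (i) every storage condition
strictly above F0 (an order relation, no margin); (ii) no incubation
condition through In4h above S2d (non-strict, so equality does not
disqualify); (iii) the In4h level within `similarity_tolerance` (default
1 log2 unit) of F0 *and* not a DEG in In4h-vs-F0. Down-markers mirror the
inequalities. The screen records every sub-check, treats absent candidates
as recorded failures, and is monotone in the tolerance: raising it never
turns a pass into a fail.

Level comparisons across conditions need a composition-robust expression
unit: strongly regulated genes shift CPM/FPKM denominators between
conditions by up to ~1 log2 unit in simulations, so
`compute_expression(unit = "normalized")` (counts over median-of-ratios
size factors) is the recommended input for the screen.

A deliberate consequence of the filter: genes that *fully revert* by In4h
are indistinguishable from markers — that is what the filter means. Marker
recovery experiments therefore plant markers alongside null and
persistent (monotone-diapause) genes; reversal-class genes are assessed by
the regression machinery instead.

`proliferation_tally()` cross-tabulates DEG direction with
negative/positive proliferation-regulation gene sets and flags the
proliferation-arrest signature via a continuity-corrected odds ratio.
`ddct()` implements 2^-ΔΔCt relative quantification exactly and is
invariant to adding a constant to all four Ct values.

## Phosphoproteomics and KSEA

`normalize_phospho()` log2-transforms and subtracts each sample's median
(ratio scaling on the raw scale), leaving every sample median exactly
zero; the operation is idempotent. Median subtraction on the log scale was
chosen over the raw scale because it corresponds to a multiplicative
loading correction. `call_regulated()` uses the joint rule
|FC| > 1.5 with a pooled-variance Student t-test p < 0.05 (both strict).

`ksea()` ranks all quantified phosphopeptides by log2 fold change (ties
broken by peptide id for determinism) and computes the weighted
Kolmogorov–Smirnov running-sum enrichment score with weight exponent 1:
hits step up by `|r| / sum(|r| over hits)`, misses step down by
`1/(N - N_hits)`; the ES is the signed maximum deviation. Running-sum
extremes occur only just after a hit (maxima) or just before one (minima),
so the implementation evaluates those 2m points; magnitude ties — which
arise structurally because some extremes are pure miss-count fractions —
resolve toward the positive extreme with an explicit 1e-9 tolerance.

The null distribution permutes substrate-set membership over peptides
(gene-set permutation): with three replicates per condition, sample
permutation has far too few distinct relabelings. NES divides the ES by
the mean magnitude of same-sign null scores, so NES > 1 reads as positive
enrichment in the shifted (diapause) condition; the permutation p is the
smoothed same-sign tail `(1 + k)/(1 + n_same)`, bounded below by
`1/(n_perm + 1)`. Kinases with fewer matched peptides than
`min_kinase_set_size` (default 3) or whose substrates span the whole
ranking (undefined miss decrement) are excluded with a warning.
Site matching is exact on (protein, residue, position); peptides may count
in several kinases' sets, and a multi-site peptide matches a kinase if any
site matches. An `exact = TRUE` mode enumerates all substrate-label
assignments for small problems and is checked against an independent
brute-force oracle in the tests.

## OPLS-DA and the VIP screen

`fit_oplsda()` implements two-class orthogonal projections to latent
structures: variables are mean-centred and unit-variance scaled (Pareto
and no scaling are exposed), the class response is coded ±1 and centred,
one orthogonal component is removed by default (standard for two-class
problems; configurable), and one predictive component is fitted on the
filtered matrix. With a single y the NIPALS weight vector is exact in one
pass, so the nominal convergence controls (tolerance 1e-10, 500
iterations) never bind for discriminant analysis. Predictive scores are
numerically orthogonal to every orthogonal score (inner products below
1e-8 in tests).

VIP is computed on the single predictive component, which reduces to
`vip_j = sqrt(p) |w_j| / ||w||`, so `sum(vip^2) = p` identically.
`screen_metabolites()` applies the joint rule VIP > 1 and Student t-test
p < 0.05, and separately reports the VIP-positive/t-negative tier, which
is the expected outcome when group separation is driven by orthogonal
structure rather than mean shifts. Under a null (no planted shift) the
joint selection rate per metabolite sits at the nominal t-test level
(~5%); with 20 metabolites the minimum of 20 uniform p-values is below
0.05 in about two thirds of datasets, so *some* joint selections under the
null are expected and zero-selection in most datasets is not an attainable
bar.

## The synthetic-data generators

`simulate_counts()` draws NB counts with `mu = base_mean_g * sf_s *
2^signal`, a single global dispersion (default 0.1), per-sample size
factors uniform on [0.7, 1.3], and per-gene baselines log-normal around
`base_mean` (sdlog 0.5) so the mean–dispersion trend fit is exercised.
Gene classes plant the study's structure:

* `null` — no signal anywhere;
* `up_diapause` / `down_diapause` — ±`effect_lfc` (default 2) in every
  storage condition, persisting through incubation;
* `marker_up` / `marker_down` — the same diapause effect, decaying during
  incubation to 0.5/0.25/0.1 of the effect at In0.5h/In1h/In2h and exactly
  the F0 level from In4h on. The decay fractions give the marker screen's
  condition (ii) a real margin instead of an expectation-level equality;
* `reversal` — diapause effects with random sign and magnitude uniform on
  `effect_lfc ± 1` (floored at 1); during incubation the expected log2FC
  versus S2d is `slope_schedule[t]` times the F0-vs-S2d log2FC plus
  Gaussian noise (sd 0.5 by default, chosen so Pearson R over ~280 genes
  lands in the R > 0.5 regime — a tunable, not a claim). The default
  schedule anchors the reactivation slopes 0.2/0.45/0.79 at In1h/In2h/In4h
  and continues 0.85/0.9 at In6h/In12h.

`simulate_phospho()` draws log2 intensities Gaussian around per-peptide
baselines (noise sd 0.3), shifts the substrates of each active kinase by
its δ in the second design condition, samples residues S/T/Y at
0.86/0.126/0.014, and returns the matching kinase–substrate map.
`simulate_metabolites()` draws log-normal abundances with within-group
log-sd 0.3 and shifts selected metabolites between groups in sd units;
six samples per group is the default panel size, typical for targeted
metabolomics.

Replicate-level variance parameters are not reported for the real data the
generators emulate, so all noise defaults are *declared*, not fitted. The
generators do not model batch effects, missing TMT channels, library
composition beyond what the planted classes induce, or count–length
biases, so passing tests demonstrate correctness of the statistical
machinery under the declared model, not performance on any real dataset.
Seeds are mandatory; identical seeds give bit-identical outputs.

## Problem sizes and numerical choices

The test and acceptance workloads use desk-scale problems chosen to give
stable operating characteristics: 280-gene reversal panels over 100 seeds,
2000-gene null calibrations over 20 seeds, 1000-gene reactivation courses
over 50 seeds, 300-peptide phosphoproteomes with 1000 permutations over 50
seeds, and 20-metabolite panels over 100 seeds. Measured behaviour at these
sizes: null false-positive rate ≈ 0.047 at p < 0.05, zero calls at
FDR < 0.01 under the null, ≥ 90% power for 4-fold effects at base mean
100, slope recovery within ±0.1 at every scheduled time point, perfect
marker sensitivity/specificity at 2-log2 margins with ~0.25 log2 noise,
and KSEA null p-values within binomial bounds of nominal.

Degenerate inputs fail loudly and specifically: all-zero libraries,
missing design samples, out-of-range thresholds (named field), nonpositive
phospho intensities (named peptide), substrate sets spanning the whole
ranking, zero-variance metabolites (removed with a warning), and
single-group OPLS-DA are all rejected rather than silently repaired.

## Known limitations

* The DEG caller's moderated-t reference is a pragmatic calibration device,
  not an exact small-sample theory; extremely unbalanced or two-condition
  designs fall back to fewer dispersion df and correspondingly heavier
  tails.
* KSEA assumes the ranking metric is exchangeable across peptides under the
  null of no kinase activity; peptide-level correlation within a protein is
  not modelled.
* OPLS-DA is fitted with a single predictive component and is intended for
  two-class designs only.
* The marker filter cannot, by construction, distinguish a marker from any
  gene that fully reverts by In4h without overshooting S2d.
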