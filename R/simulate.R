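#' @name simulate
#' @title Synthetic multi-omic time courses with planted structure
#' @description Generators for every input type the pipeline consumes:
#'   negative-binomial RNA-seq counts with planted diapause-monotone, marker
#'   and reversal gene classes; two-condition phosphopeptide tables with
#'   kinase-driven shifts; and two-group metabolite matrices with planted
#'   mean shifts. All generators are deterministic given their seed and
#'   return a truth table covering every planted entity.
NULL

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Specification for the RNA-seq count simulator
#'
#' Counts are drawn NB(mu, alpha) with `Var = mu + alpha * mu^2` and
#' `mu_gs = base_mean_g * sf_s * 2^signal_gc`. Gene classes:
#' \describe{
#'   \item{null}{signal 0 everywhere.}
#'   \item{up_diapause / down_diapause}{signal +/-`effect_lfc` in every
#'     storage condition versus F0, persisting through incubation.}
#'   \item{marker_up / marker_down}{diapause signal as above, decaying during
#'     incubation (fractions 0.5, 0.25, 0.1 of the effect at In0.5h, In1h,
#'     In2h) and exactly back to the F0 level from In4h on, never
#'     overshooting the S2d level.}
#'   \item{reversal}{diapause effect with random sign and magnitude uniform
#'     on `effect_lfc + c(-1, 1)` (floored at 1); during incubation the
#'     expected log2FC versus S2d equals `slope_schedule[t]` times the
#'     F0-vs-S2d log2FC, plus Gaussian noise (`reversal_noise_sd`).}
#' }
#'
#' @param n_genes Number of genes.
#' @param gene_class_fractions Named proportions over classes `null`,
#'   `up_diapause`, `down_diapause`, `marker_up`, `marker_down`, `reversal`;
#'   must sum to 1.
#' @param base_mean Median expected count of the per-gene log-normal
#'   baseline. Default 100.
#' @param base_mean_sdlog sdlog of the per-gene baseline spread. Default 0.5.
#' @param dispersion NB dispersion alpha. Default 0.1.
#' @param effect_lfc Planted |log2FC| for diapause classes. Default 2.
#' @param slope_schedule Named vector, incubation condition -> target
#'   reversal slope in `[0, 1]`. Conditions absent from the schedule get the
#'   last scheduled value carried forward (0 before the first).
#' @param reversal_noise_sd Gaussian sd (log2 units) of the per-gene,
#'   per-condition reversal targets. Default 0.5.
#' @param size_factor_range Uniform range of per-sample size factors.
#' @param n_replicates Replicates per condition. Default 3.
#' @param rng_seed Mandatory integer seed.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_genes = 2000,
                     gene_class_fractions = c(
                       null = 0.70, up_diapause = 0.08, down_diapause = 0.08,
                       marker_up = 0.02, marker_down = 0.02, reversal = 0.10
                     ),
                     base_mean = 100,
                     base_mean_sdlog = 0.5,
                     dispersion = 0.1,
                     effect_lfc = 2,
                     slope_schedule = c(
                       "In0.5h" = 0.1, "In1h" = 0.2, "In2h" = 0.45,
                       "In4h" = 0.79, "In6h" = 0.85, "In12h" = 0.9
                     ),
                     reversal_noise_sd = 0.5,
                     size_factor_range = c(0.7, 1.3),
                     n_replicates = 3,
                     rng_seed) {
  classes <- c("null", "up_diapause", "down_diapause",
               "marker_up", "marker_down", "reversal")
  if (missing(rng_seed)) abort("sim_spec requires an explicit rng_seed")
  fr <- gene_class_fractions
  unknown <- setdiff(names(fr), classes)
  if (length(unknown) > 0) {
    abort(paste0("unknown gene class(es): ", paste(unknown, collapse = ", ")))
  }
  full <- setNames(numeric(length(classes)), classes)
  full[names(fr)] <- fr
  if (abs(sum(full) - 1) > 1e-9) {
    abort("gene_class_fractions must sum to 1")
  }
  if (any(full < 0)) abort("gene_class_fractions must be non-negative")
  if (any(slope_schedule < 0 | slope_schedule > 1)) {
    abort("slope_schedule values must lie in [0, 1]")
  }
  bad_sched <- setdiff(names(slope_schedule), incubation_conditions())
  if (length(bad_sched) > 0) {
    abort(paste0("slope_schedule names must be incubation conditions; got ",
                 paste(bad_sched, collapse = ", ")))
  }
  stopifnot(n_genes >= 1, base_mean > 0, dispersion > 0, effect_lfc > 0,
            reversal_noise_sd >= 0, n_replicates >= 1,
            length(size_factor_range) == 2,
            all(size_factor_range > 0),
            size_factor_range[1] <= size_factor_range[2])
  structure(
    list(
      n_genes = as.integer(n_genes),
      gene_class_fractions = full,
      base_mean = base_mean,
      base_mean_sdlog = base_mean_sdlog,
      dispersion = dispersion,
      effect_lfc = effect_lfc,
      slope_schedule = slope_schedule,
      reversal_noise_sd = reversal_noise_sd,
      size_factor_range = size_factor_range,
      n_replicates = as.integer(n_replicates),
      rng_seed = as.integer(rng_seed)
    ),
    class = "sim_spec"
  )
}

# marker decay: fraction of the diapause effect remaining during incubation
marker_decay <- c("In0.5h" = 0.5, "In1h" = 0.25, "In2h" = 0.1,
                  "In4h" = 0, "In6h" = 0, "In12h" = 0)

# slope for an incubation condition: scheduled value, else carry-forward
schedule_slope <- function(schedule, condition) {
  if (condition %in% names(schedule)) return(schedule[[condition]])
  inc <- incubation_conditions()
  pos <- match(condition, inc)
  sched_pos <- match(names(schedule), inc)
  before <- sched_pos[sched_pos < pos]
  if (length(before) == 0) return(0)
  schedule[[names(schedule)[which(sched_pos == max(before))]]]
}

#' Simulate an RNA-seq count time course with planted gene classes
#'
#' @param spec A [sim_spec()].
#' @param design Sample design; must contain F0, at least two storage
#'   conditions, and S2d whenever incubation conditions are present.
#' @return A list with elements `counts` (wide count tibble), `truth`
#'   (per-gene tibble: `gene_id`, `class`, `base_mean`, `planted_lfc`), and
#'   `signal` (genes x conditions matrix of planted log2 offsets from F0,
#'   including the realised reversal noise), plus the design and the
#'   per-sample `size_factors` used.
#' @export
#' @examples
#' des <- diapause_design(c("F0", "S1d", "S2d"), n_replicates = 2)
#' sim <- simulate_counts(sim_spec(n_genes = 50, rng_seed = 1), des)
#' table(sim$truth$class)
simulate_counts <- function(spec, design) {
  stopifnot(inherits(spec, "sim_spec"))
  design <- validate_design(design)
  conds <- unique(design$condition)
  if (!"F0" %in% conds) abort("design must contain condition F0")
  n_storage <- sum(setdiff(conds, "F0") %in% storage_conditions())
  if (n_storage < 2) abort("design needs at least two storage conditions")
  inc_present <- intersect(conds, incubation_conditions())
  if (length(inc_present) > 0 && !"S2d" %in% conds) {
    abort("incubation conditions require S2d in the design")
  }

  with_seed(spec$rng_seed, {
    n <- spec$n_genes
    # deterministic class sizes from fractions (largest-remainder rounding)
    target <- spec$gene_class_fractions * n
    sizes <- floor(target)
    rem <- n - sum(sizes)
    if (rem > 0) {
      ord <- order(target - sizes, decreasing = TRUE)
      sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1
    }
    class_vec <- rep(names(sizes), times = sizes)
    gene_ids <- sprintf("G%05d", seq_len(n))

    base_mean_g <- spec$base_mean *
      exp(rnorm(n, 0, spec$base_mean_sdlog))

    d <- numeric(n)
    d[class_vec == "up_diapause"]   <-  spec$effect_lfc
    d[class_vec == "down_diapause"] <- -spec$effect_lfc
    d[class_vec == "marker_up"]     <-  spec$effect_lfc
    d[class_vec == "marker_down"]   <- -spec$effect_lfc
    is_rev <- class_vec == "reversal"
    n_rev <- sum(is_rev)
    if (n_rev > 0) {
      mag <- runif(n_rev, max(1, spec$effect_lfc - 1), spec$effect_lfc + 1)
      sgn <- sample(c(-1, 1), n_rev, replace = TRUE)
      d[is_rev] <- sgn * mag
    }

    signal <- matrix(0, n, length(conds), dimnames = list(gene_ids, conds))
    for (cond in conds) {
      if (cond == "F0") next
      if (cond %in% storage_conditions()) {
        signal[, cond] <- d
      } else {
        dec <- marker_decay[[cond]]
        slp <- schedule_slope(spec$slope_schedule, cond)
        col <- d  # persistent diapause level by default
        mk <- class_vec %in% c("marker_up", "marker_down")
        col[mk] <- d[mk] * dec
        if (n_rev > 0) {
          # E[log2FC(In vs S2d)] = slope * log2FC(F0 vs S2d) = slope * (-d)
          col[is_rev] <- d[is_rev] * (1 - slp) +
            rnorm(n_rev, 0, spec$reversal_noise_sd)
        }
        col[class_vec == "null"] <- 0
        signal[, cond] <- col
      }
    }

    sf <- runif(nrow(design), spec$size_factor_range[1],
                spec$size_factor_range[2])
    names(sf) <- design$sample_id
    mu <- (base_mean_g * 2^signal[, design$condition, drop = FALSE]) *
      rep(sf, each = n)
    counts <- matrix(
      rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion),
      n, nrow(design), dimnames = list(gene_ids, design$sample_id)
    )

    list(
      counts = matrix_to_wide(counts, "gene_id"),
      truth = tibble::tibble(
        gene_id = gene_ids, class = class_vec,
        base_mean = base_mean_g, planted_lfc = d
      ),
      signal = signal,
      design = design,
      size_factors = sf
    )
  })
}

#' Specification for the phosphopeptide simulator
#'
#' @param n_peptides Number of phosphopeptides. Default 500.
#' @param n_kinases Number of kinases in the substrate map. Default 10.
#' @param substrates_per_kinase Substrate peptides per kinase (disjoint
#'   across kinases). Default 6.
#' @param active_kinases Named numeric vector of log2 shifts delta applied to
#'   each active kinase's substrates in the shifted (diapause) condition.
#'   Default none.
#' @param noise_sd Within-peptide log2 intensity sd. Default 0.3.
#' @param residue_probs Sampling probabilities for S/T/Y sites; the default
#'   0.86/0.126/0.014 mirrors the residue split typically observed in
#'   MS phosphoproteomes.
#' @param rng_seed Mandatory integer seed.
#' @return A list of class `phospho_sim_spec`.
#' @export
phospho_sim_spec <- function(n_peptides = 500,
                             n_kinases = 10,
                             substrates_per_kinase = 6,
                             active_kinases = c(),
                             noise_sd = 0.3,
                             residue_probs = c(S = 0.86, T = 0.126, Y = 0.014),
                             rng_seed) {
  if (missing(rng_seed)) abort("phospho_sim_spec requires an explicit rng_seed")
  if (substrates_per_kinase * n_kinases > n_peptides) {
    abort("substrates_per_kinase * n_kinases exceeds n_peptides")
  }
  if (abs(sum(residue_probs) - 1) > 1e-9 || any(residue_probs < 0)) {
    abort("residue_probs must be non-negative and sum to 1")
  }
  kin_ids <- sprintf("KIN%02d", seq_len(n_kinases))
  if (length(active_kinases) > 0) {
    if (is.null(names(active_kinases)) ||
        !all(names(active_kinases) %in% kin_ids)) {
      abort("active_kinases must be named with declared kinase ids (KINxx)")
    }
  }
  stopifnot(noise_sd > 0)
  structure(
    list(
      n_peptides = as.integer(n_peptides),
      n_kinases = as.integer(n_kinases),
      substrates_per_kinase = as.integer(substrates_per_kinase),
      active_kinases = active_kinases,
      noise_sd = noise_sd,
      residue_probs = residue_probs,
      rng_seed = as.integer(rng_seed)
    ),
    class = "phospho_sim_spec"
  )
}

#' Simulate a two-condition phosphopeptide experiment
#'
#' Log2 intensities are Gaussian around a per-peptide baseline; substrates of
#' each active kinase are shifted by its delta in the second condition of the
#' design (the diapause condition). Intensities are returned on the raw
#' scale, ready for [normalize_phospho()].
#'
#' @param spec A [phospho_sim_spec()].
#' @param design Two-condition design with >= 3 replicates each; the second
#'   condition in design order receives the shifts.
#' @return A list with `phospho` (wide phospho tibble), `map`
#'   (kinase-substrate tibble), and `truth` (per-peptide tibble with the
#'   assigned kinase and planted shift).
#' @export
simulate_phospho <- function(spec, design) {
  stopifnot(inherits(spec, "phospho_sim_spec"))
  design <- validate_design(design)
  conds <- unique(design$condition)
  if (length(conds) != 2) abort("phospho design must have exactly 2 conditions")
  reps <- table(design$condition)
  if (any(reps < 3)) abort("each condition needs >= 3 replicates")

  with_seed(spec$rng_seed, {
    n <- spec$n_peptides
    pep_ids <- sprintf("PEP%05d", seq_len(n))
    n_prot <- ceiling(n / 2)
    prot_ids <- sprintf("PROT%05d", sample(rep(seq_len(n_prot), length.out = n)))
    residues <- sample(names(spec$residue_probs), n, replace = TRUE,
                       prob = spec$residue_probs)
    # unique positions within each protein
    positions <- integer(n)
    for (p in unique(prot_ids)) {
      idx <- which(prot_ids == p)
      positions[idx] <- sort(sample.int(500, length(idx))) * 2 + 1
    }

    kin_ids <- sprintf("KIN%02d", seq_len(spec$n_kinases))
    assigned <- sample.int(n, spec$n_kinases * spec$substrates_per_kinase)
    kinase_of <- rep(NA_character_, n)
    kinase_of[assigned] <- rep(kin_ids, each = spec$substrates_per_kinase)

    shift <- numeric(n)
    for (k in names(spec$active_kinases)) {
      shift[!is.na(kinase_of) & kinase_of == k] <- spec$active_kinases[[k]]
    }

    base <- rnorm(n, 20, 2)
    shifted_cond <- conds[2]
    log2_int <- vapply(design$sample_id, function(s) {
      cond <- design$condition[design$sample_id == s]
      mu <- base + if (cond == shifted_cond) shift else 0
      rnorm(n, mu, spec$noise_sd)
    }, numeric(n))
    rownames(log2_int) <- pep_ids

    phospho <- dplyr::bind_cols(
      tibble::tibble(
        peptide_id = pep_ids,
        protein_id = prot_ids,
        sites = paste0(residues, positions)
      ),
      tibble::as_tibble(2^log2_int, .name_repair = "minimal")
    )

    map <- tibble::tibble(
      kinase_id = kinase_of[assigned],
      protein_id = prot_ids[assigned],
      residue = residues[assigned],
      position = positions[assigned]
    )
    map <- dplyr::arrange(map, .data$kinase_id, .data$protein_id,
                          .data$position)

    list(
      phospho = phospho,
      map = map,
      truth = tibble::tibble(
        peptide_id = pep_ids, protein_id = prot_ids,
        residue = residues, position = positions,
        kinase_id = kinase_of, planted_shift = shift
      ),
      shifted_condition = shifted_cond
    )
  })
}

#' Simulate a two-group metabolite panel
#'
#' Abundances are log-normal; `n_shifted` metabolites differ between groups
#' by `shift` within-group standard deviations on the log scale (shift
#' applied to group B).
#'
#' @param n_metabolites Panel size. Default 20.
#' @param n_shifted Number of shifted metabolites. Default 2.
#' @param shift Group-mean difference in within-group sd units. Default 3.
#' @param n_per_group Samples per group (>= 3). Default 6.
#' @param seed Integer seed.
#' @param within_sd Within-group sd on the natural-log scale. Default 0.3.
#' @return A list with `matrix` (wide metabolite tibble), `groups`
#'   (`sample_id`, `group` tibble) and `truth` (character vector of shifted
#'   metabolite ids).
#' @export
simulate_metabolites <- function(n_metabolites = 20, n_shifted = 2,
                                 shift = 3, n_per_group = 6, seed,
                                 within_sd = 0.3) {
  if (missing(seed)) abort("simulate_metabolites requires an explicit seed")
  if (n_shifted > n_metabolites) abort("n_shifted exceeds n_metabolites")
  if (n_per_group < 3) abort("n_per_group must be >= 3")
  with_seed(seed, {
    met_ids <- sprintf("MET%03d", seq_len(n_metabolites))
    sample_ids <- c(paste0("A_r", seq_len(n_per_group)),
                    paste0("B_r", seq_len(n_per_group)))
    groups <- tibble::tibble(
      sample_id = sample_ids,
      group = rep(c("A", "B"), each = n_per_group)
    )
    base <- rnorm(n_metabolites, 10, 1)
    shifted <- if (n_shifted > 0) {
      sort(sample(met_ids, n_shifted))
    } else character(0)
    delta <- ifelse(met_ids %in% shifted, shift * within_sd, 0)
    logab <- vapply(seq_along(sample_ids), function(i) {
      mu <- base + if (groups$group[i] == "B") delta else 0
      rnorm(n_metabolites, mu, within_sd)
    }, numeric(n_metabolites))
    m <- exp(logab)
    dimnames(m) <- list(met_ids, sample_ids)
    list(
      matrix = matrix_to_wide(m, "metabolite_id"),
      groups = groups,
      truth = shifted
    )
  })
}
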