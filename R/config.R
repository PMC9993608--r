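#' Analysis configuration
#'
#' Bundles the thresholds and tuning constants used across the pipeline. The
#' defaults are the study cutoffs: DEGs at FDR < 0.01 with |log2 fold change|
#' > 1; phosphopeptides regulated at > 1.5-fold with t-test p < 0.05;
#' metabolites screened at VIP > 1; 150 random control genes for gene-set
#' fold-change summaries.
#'
#' @param fdr_threshold DEG FDR cutoff, in (0,1). Default 0.01.
#' @param lfc_threshold DEG |log2FC| cutoff, non-negative. Default 1.
#' @param phospho_fc_threshold Phosphopeptide fold-change cutoff (> 1, linear
#'   scale). Default 1.5.
#' @param phospho_p_threshold Phosphopeptide t-test p cutoff, in (0,1).
#'   Default 0.05.
#' @param vip_threshold VIP cutoff for the metabolite screen (> 0). Default 1.
#' @param n_permutations Permutations for KSEA null distributions. Default 1000.
#' @param rng_seed Integer seed used wherever the configured analysis draws
#'   random numbers (control-gene sampling, KSEA permutations).
#' @param control_set_size Random control genes for gene-set summaries.
#'   Default 150.
#' @param min_kinase_set_size Minimum matched substrate peptides for a kinase
#'   to be tested. Default 3.
#' @param similarity_tolerance Marker condition (iii) |log2 ratio| tolerance
#'   (log2 units). Default 1.
#' @return A list of class `run_config`.
#' @export
#' @examples
#' run_config(rng_seed = 1)
run_config <- function(fdr_threshold = 0.01,
                       lfc_threshold = 1,
                       phospho_fc_threshold = 1.5,
                       phospho_p_threshold = 0.05,
                       vip_threshold = 1,
                       n_permutations = 1000,
                       rng_seed = 1L,
                       control_set_size = 150,
                       min_kinase_set_size = 3,
                       similarity_tolerance = 1) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) abort(paste0("run_config field '", field, "' ", msg))
  }
  chk(is.numeric(fdr_threshold) && fdr_threshold > 0 && fdr_threshold < 1,
      "fdr_threshold", "must be in (0, 1)")
  chk(is.numeric(lfc_threshold) && lfc_threshold >= 0,
      "lfc_threshold", "must be non-negative")
  chk(is.numeric(phospho_fc_threshold) && phospho_fc_threshold > 1,
      "phospho_fc_threshold", "must be > 1")
  chk(is.numeric(phospho_p_threshold) && phospho_p_threshold > 0 &&
        phospho_p_threshold < 1,
      "phospho_p_threshold", "must be in (0, 1)")
  chk(is.numeric(vip_threshold) && vip_threshold > 0,
      "vip_threshold", "must be > 0")
  chk(is.numeric(n_permutations) && n_permutations >= 1,
      "n_permutations", "must be a positive integer")
  chk(is.numeric(rng_seed) && is.finite(rng_seed),
      "rng_seed", "must be an integer")
  chk(is.numeric(control_set_size) && control_set_size >= 1,
      "control_set_size", "must be a positive integer")
  chk(is.numeric(min_kinase_set_size) && min_kinase_set_size >= 1,
      "min_kinase_set_size", "must be a positive integer")
  chk(is.numeric(similarity_tolerance) && similarity_tolerance >= 0,
      "similarity_tolerance", "must be non-negative")
  structure(
    list(
      fdr_threshold = fdr_threshold,
      lfc_threshold = lfc_threshold,
      phospho_fc_threshold = phospho_fc_threshold,
      phospho_p_threshold = phospho_p_threshold,
      vip_threshold = vip_threshold,
      n_permutations = as.integer(n_permutations),
      rng_seed = as.integer(rng_seed),
      control_set_size = as.integer(control_set_size),
      min_kinase_set_size = as.integer(min_kinase_set_size),
      similarity_tolerance = similarity_tolerance
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a key = value text file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments and blank
#' lines ignored. Unknown keys are rejected; values are validated by
#' [run_config()].
#'
#' @param path File path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[=:]", fixed = FALSE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    abort(paste0("cannot parse config line: '", lines[bad][1], "'"))
  }
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  known <- names(formals(run_config))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  args <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) abort(paste0("non-numeric config value: '", v, "'"))
    num
  })
  names(args) <- keys
  do.call(run_config, args)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
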