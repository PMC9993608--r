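#' @name io
#' @title Tab-separated readers and writers
#' @description All tables are tab-separated UTF-8 with a mandatory header.
#'   Count and expression matrices are stored wide: a `gene_id` first column
#'   followed by one column per sample. Gene identifiers are opaque,
#'   case-sensitive strings; no symbol/accession mapping is attempted.
NULL

# internal: wide tibble (id column + numeric columns) -> numeric matrix
wide_to_matrix <- function(tbl, id_col) {
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  rownames(m) <- tbl[[id_col]]
  storage.mode(m) <- "double"
  m
}

matrix_to_wide <- function(m, id_col = "gene_id") {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(!!id_col := rownames(m)), out)
  out
}

#' Read a gene-level count matrix
#'
#' @param path TSV with a `gene_id` header column and one column per sample.
#' @param design Sample design; every design `sample_id` must be present as a
#'   column. Extra columns are dropped; column order is reordered to match the
#'   design.
#' @return A wide count tibble (`gene_id` + one integer-valued column per
#'   design sample).
#' @export
read_count_matrix <- function(path, design) {
  design <- validate_design(design)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(tbl)[1] != "gene_id") {
    names(tbl)[1] <- "gene_id"
  }
  missing <- setdiff(design$sample_id, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("count matrix is missing sample column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tbl <- tbl[c("gene_id", design$sample_id)]
  validate_counts(tbl)
}

#' Validate a wide count tibble
#'
#' Requires unique gene ids, no missing cells, and non-negative integer-valued
#' counts; names the offending cell on failure.
#'
#' @param counts Wide count tibble (`gene_id` + sample columns).
#' @return The validated tibble.
#' @export
validate_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  if (names(counts)[1] != "gene_id") {
    abort("first column of a count table must be 'gene_id'")
  }
  if (anyDuplicated(counts$gene_id)) {
    abort("gene_id values must be unique")
  }
  m <- wide_to_matrix(counts, "gene_id")
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-integer or negative count at gene '%s', sample '%s'",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]
    ))
  }
  counts
}

#' @rdname read_count_matrix
#' @param counts Wide count tibble to write.
#' @export
write_count_matrix <- function(counts, path) {
  readr::write_tsv(validate_counts(counts), path, progress = FALSE)
  invisible(path)
}

#' Read / write a sample-design table
#' @param path TSV with columns `sample_id`, `condition`, `replicate`,
#'   `time_value`, `series`.
#' @return A validated design tibble.
#' @export
read_sample_design <- function(path) {
  validate_design(readr::read_tsv(path, show_col_types = FALSE,
                                  progress = FALSE))
}

#' @rdname read_sample_design
#' @param design Design tibble to write.
#' @export
write_sample_design <- function(design, path) {
  readr::write_tsv(validate_design(design), path, progress = FALSE)
  invisible(path)
}

#' Read / write gene-set annotations
#'
#' Long format: one row per (term, gene), columns `term_id`, `term_name`,
#' `gene_id` (e.g. positive/negative regulation of cell proliferation sets).
#'
#' @param path TSV path.
#' @return A tibble with columns `term_id`, `term_name`, `gene_id`.
#' @export
read_gene_sets <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_gene_sets(tbl)
}

validate_gene_sets <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  miss <- setdiff(c("term_id", "term_name", "gene_id"), names(tbl))
  if (length(miss) > 0) {
    abort(paste0("gene-set table missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(tbl) == 0) abort("gene-set table is empty")
  nm <- dplyr::distinct(tbl, .data$term_id, .data$term_name)
  if (anyDuplicated(nm$term_id)) {
    abort("term_id maps to more than one term_name")
  }
  tbl
}

#' @rdname read_gene_sets
#' @param gene_sets Tibble to write.
#' @export
write_gene_sets <- function(gene_sets, path) {
  readr::write_tsv(validate_gene_sets(gene_sets), path, progress = FALSE)
  invisible(path)
}

#' Read / write a phosphopeptide quantification table
#'
#' Columns `peptide_id`, `protein_id`, `sites` (semicolon-joined
#' residue+position codes such as `"S10"` or `"S10;T14"`), then one intensity
#' column per sample (raw scale, positive).
#'
#' @param path TSV path.
#' @return A phospho tibble.
#' @export
read_phospho_table <- function(path) {
  validate_phospho(readr::read_tsv(path, show_col_types = FALSE,
                                   progress = FALSE))
}

validate_phospho <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  miss <- setdiff(c("peptide_id", "protein_id", "sites"), names(tbl))
  if (length(miss) > 0) {
    abort(paste0("phospho table missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(tbl$peptide_id)) abort("peptide_id values must be unique")
  if (any(!nzchar(tbl$sites))) abort("every phosphopeptide needs >=1 site")
  bad <- !grepl("^([STY][0-9]+)(;[STY][0-9]+)*$", tbl$sites)
  if (any(bad)) {
    abort(paste0("malformed sites field for peptide '",
                 tbl$peptide_id[bad][1], "': '", tbl$sites[bad][1], "'"))
  }
  tbl
}

#' @rdname read_phospho_table
#' @param phospho Tibble to write.
#' @export
write_phospho_table <- function(phospho, path) {
  readr::write_tsv(validate_phospho(phospho), path, progress = FALSE)
  invisible(path)
}

# expand the sites column: one row per (peptide, residue, position)
phospho_sites_long <- function(phospho) {
  long <- tidyr::separate_rows(
    phospho[c("peptide_id", "protein_id", "sites")], "sites", sep = ";"
  )
  dplyr::transmute(long,
    peptide_id = .data$peptide_id,
    protein_id = .data$protein_id,
    residue    = substr(.data$sites, 1, 1),
    position   = as.integer(substring(.data$sites, 2))
  )
}

#' Read / write a kinase-substrate map
#'
#' Three columns: `kinase_id`, `protein_id`, `site` (residue+position, e.g.
#' `"S10"`), the format produced by site-prediction tools such as iGPS.
#'
#' @param path TSV path.
#' @return A tibble with columns `kinase_id`, `protein_id`, `residue`,
#'   `position`.
#' @export
read_kinase_substrate_map <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("kinase_id", "protein_id", "site"), names(tbl))
  if (length(miss) > 0) {
    abort(paste0("kinase-substrate map missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  bad <- !grepl("^[STY][0-9]+$", tbl$site)
  if (any(bad)) {
    abort(paste0("malformed site '", tbl$site[bad][1], "' in substrate map"))
  }
  dplyr::transmute(tbl,
    kinase_id  = .data$kinase_id,
    protein_id = .data$protein_id,
    residue    = substr(.data$site, 1, 1),
    position   = as.integer(substring(.data$site, 2))
  )
}

#' @rdname read_kinase_substrate_map
#' @param map Tibble with columns `kinase_id`, `protein_id`, `residue`,
#'   `position` (as returned by the reader).
#' @export
write_kinase_substrate_map <- function(map, path) {
  out <- dplyr::transmute(map,
    kinase_id  = .data$kinase_id,
    protein_id = .data$protein_id,
    site       = paste0(.data$residue, .data$position)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write a metabolite abundance matrix
#'
#' Wide format: `metabolite_id` first column, then one positive abundance
#' column per sample; group membership travels in a separate two-column
#' `sample_id`, `group` table.
#'
#' @param path TSV path.
#' @return A wide metabolite tibble.
#' @export
read_metabolite_matrix <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(tbl)[1] != "metabolite_id") names(tbl)[1] <- "metabolite_id"
  if (anyDuplicated(tbl$metabolite_id)) {
    abort("metabolite_id values must be unique")
  }
  m <- wide_to_matrix(tbl, "metabolite_id")
  if (any(!is.finite(m)) || any(m <= 0)) {
    abort("metabolite abundances must be positive and complete")
  }
  tbl
}

#' @rdname read_metabolite_matrix
#' @param matrix Wide metabolite tibble.
#' @export
write_metabolite_matrix <- function(matrix, path) {
  readr::write_tsv(matrix, path, progress = FALSE)
  invisible(path)
}
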