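# Readers and writers for every tabular artifact of the pipeline:
# tab-separated matrices, annotations and pairwise similarities,
# comma-separated sample metadata. Writers stamp a header comment naming
# the producing operation; readers skip comment lines, so fixtures written
# here and tables produced elsewhere are interchangeable.

io_header <- function(op) {
  sprintf("# produced_by: %s votuecol %s", op,
          as.character(utils::packageVersion("votuecol")))
}

#' Read / write a vOTU x sample abundance matrix (TSV)
#'
#' The file holds vOTU ids in the first column and one column per sample.
#' Values must be numeric and non-negative; duplicated vOTU or sample ids
#' are rejected.
#'
#' @param path File path.
#' @return `read_abundance_matrix()`: a numeric matrix with vOTU rownames
#'   and sample colnames.
#' @export
read_abundance_matrix <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (ncol(df) < 2) abort("abundance table needs an id column and >= 1 sample.")
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated vOTU id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  if (anyDuplicated(names(df)[-1])) abort("duplicated sample ids in header.")
  vals <- df[-1]
  num <- suppressWarnings(purrr::map(vals, as.numeric))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]) & !is.na(vals[[j]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric cell at row %d, column '%s'.",
                    bad[1], names(vals)[j]))
    }
  }
  m <- do.call(cbind, num)
  rownames(m) <- ids
  colnames(m) <- names(vals)
  if (anyNA(m)) abort("missing values in abundance matrix.")
  if (any(m < 0)) abort("negative abundance values are not allowed.")
  m
}

#' @rdname read_abundance_matrix
#' @param x Matrix to write.
#' @param id_column Name of the first (vOTU id) column.
#' @export
write_abundance_matrix <- function(x, path, id_column = "votu_id") {
  check_abundance_matrix(x)
  df <- tibble::as_tibble(x, rownames = id_column)
  writeLines(io_header("write_abundance_matrix"), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read / write sample metadata (CSV)
#'
#' Required columns: `sample_id` (unique), `ecosystem`, `date` (ISO-8601),
#' `total_bases` (> 0). Any further columns are carried through as
#' environmental variables.
#'
#' @param path File path.
#' @return A tibble of sample records.
#' @export
read_metadata <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("sample_id", "ecosystem", "date", "total_bases")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("metadata is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) abort("duplicated sample_id in metadata.")
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) abort("unparseable date in metadata.")
  if (any(df$total_bases <= 0)) abort("`total_bases` must be > 0.")
  df
}

#' @rdname read_metadata
#' @param metadata Tibble to write.
#' @export
write_metadata <- function(metadata, path) {
  writeLines(io_header("write_metadata"), path)
  readr::write_csv(metadata, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read / write per-contig annotation evidence (TSV)
#'
#' Required column: `contig_id`. Optional evidence columns
#' (`quality_tier`, `host_genus`, `lifestyle`, `lifestyle_probability`,
#' `recombinase_bitscore`) are validated when present; an empty table (a
#' header with no rows) is valid.
#'
#' @param path File path.
#' @return A tibble of evidence rows.
#' @export
read_annotations <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!"contig_id" %in% names(df)) {
    abort("annotations are missing required column: contig_id")
  }
  if ("lifestyle_probability" %in% names(df)) {
    p <- df$lifestyle_probability
    if (any(!is.na(p) & (p < 0 | p > 1))) {
      abort("`lifestyle_probability` must lie in [0, 1].")
    }
  }
  df
}

#' @rdname read_annotations
#' @param annotations Tibble to write.
#' @export
write_annotations <- function(annotations, path) {
  writeLines(io_header("write_annotations"), path)
  readr::write_tsv(annotations, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read / write auxiliary-gene records (TSV)
#'
#' Required columns: `contig_id`, `category`, `bit_score`, `aux_score`,
#' `amg_flags`.
#'
#' @param path File path.
#' @return A tibble of gene rows.
#' @export
read_avg_genes <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("contig_id", "category", "bit_score", "aux_score", "amg_flags")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("gene table is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  df$amg_flags <- ifelse(is.na(df$amg_flags), "", df$amg_flags)
  df
}

#' @rdname read_avg_genes
#' @param genes Tibble to write.
#' @export
write_avg_genes <- function(genes, path) {
  writeLines(io_header("write_avg_genes"), path)
  readr::write_tsv(genes, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read / write pairwise contig similarities (TSV)
#'
#' Required columns: `contig_a`, `contig_b`, `ani_percent` (0-100),
#' `aligned_fraction_shorter` (0-1); bounds are validated.
#'
#' @param path File path.
#' @return A tibble of pairwise records.
#' @export
read_pairwise_similarity <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("contig_a", "contig_b", "ani_percent", "aligned_fraction_shorter")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("similarity table is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(df$ani_percent < 0 | df$ani_percent > 100)) {
    abort("`ani_percent` must lie in [0, 100].")
  }
  if (any(df$aligned_fraction_shorter < 0 | df$aligned_fraction_shorter > 1)) {
    abort("`aligned_fraction_shorter` must lie in [0, 1].")
  }
  df
}

#' @rdname read_pairwise_similarity
#' @param similarities Tibble to write.
#' @export
write_pairwise_similarity <- function(similarities, path) {
  writeLines(io_header("write_pairwise_similarity"), path)
  readr::write_tsv(similarities, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read coverage summaries (TSV)
#'
#' Required columns: `contig_id`, `sample_id`, `trimmed_mean_depth`,
#' `breadth`; `contig_length` and `total_bases` are carried through when
#' present.
#'
#' @param path File path.
#' @return A tibble of coverage rows.
#' @export
read_coverage <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("contig_id", "sample_id", "trimmed_mean_depth", "breadth")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("coverage table is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(df$breadth < 0 | df$breadth > 1)) abort("`breadth` must lie in [0, 1].")
  if (any(df$trimmed_mean_depth < 0)) abort("`trimmed_mean_depth` must be >= 0.")
  df
}

#' @rdname read_coverage
#' @param coverage Tibble to write (a list-column `depth`, if present, is
#'   dropped).
#' @export
write_coverage <- function(coverage, path) {
  coverage <- coverage[!vapply(coverage, is.list, logical(1))]
  writeLines(io_header("write_coverage"), path)
  readr::write_tsv(coverage, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
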