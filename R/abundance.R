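# From coverage summaries to normalized vOTU abundances, and from pairwise
# contig similarities to vOTU clusters.

#' Trimmed mean of a per-position depth vector
#'
#' Sorts the vector and removes `floor(trim * length)` positions from each
#' tail before averaging — the statistic coverage tools report as
#' "trimmed mean" depth. `trim = 0` gives the arithmetic mean exactly.
#'
#' @param depth Numeric vector of per-position read depths.
#' @param trim Proportion trimmed from each tail, in `[0, 0.5)`.
#' @return The trimmed mean, a single number.
#' @examples
#' trimmed_mean(c(0, 0, 1, 1, 1, 1, 1, 1, 10, 10), trim = 0.10)  # 2
#' @export
trimmed_mean <- function(depth, trim = 0.05) {
  if (length(depth) == 0) abort("`depth` must have length >= 1.")
  if (!is.numeric(trim) || trim < 0 || trim >= 0.5) {
    abort("`trim` must be in [0, 0.5).")
  }
  k <- floor(trim * length(depth))
  s <- sort(depth)
  if (k > 0) s <- s[(k + 1):(length(s) - k)]
  mean(s)
}

#' Zero out vOTU detections below the breadth threshold
#'
#' Applies the per-sample detection rule: a contig whose breadth of coverage
#' in a sample is below `breadth_min` (default 70%, inclusive bound for
#' retention) is treated as not detected there, i.e. its trimmed-mean depth
#' is set to zero. The read-identity and read-alignment requirements of the
#' mapping step are assumed applied upstream of the coverage summary.
#'
#' @param coverage Tibble with at least `trimmed_mean_depth` and `breadth`.
#' @param breadth_min Minimum breadth retained (`breadth >= breadth_min`).
#' @return The coverage tibble with sub-threshold depths zeroed.
#' @export
apply_detection_filter <- function(coverage, breadth_min = 0.70) {
  if (!all(c("trimmed_mean_depth", "breadth") %in% names(coverage))) {
    abort("`coverage` needs columns `trimmed_mean_depth` and `breadth`.")
  }
  dplyr::mutate(
    coverage,
    trimmed_mean_depth = ifelse(.data$breadth < breadth_min, 0,
                                .data$trimmed_mean_depth)
  )
}

#' Normalize depth per metagenome gigabase
#'
#' Divides the trimmed-mean depth by the total number of quality-trimmed
#' bases of the sample and multiplies by 1e9, yielding a relative abundance
#' per metagenome gigabase. Vectorized; linear in depth and inversely
#' proportional to `total_bases`.
#'
#' @param trimmed_mean_depth Non-negative depth value(s).
#' @param total_bases Total quality-trimmed bases of the sample (> 0).
#' @return Normalized abundance(s).
#' @examples
#' normalize_per_gigabase(3.5, 7e9)  # 0.5
#' @export
normalize_per_gigabase <- function(trimmed_mean_depth, total_bases) {
  if (any(!is.finite(total_bases)) || any(total_bases <= 0)) {
    abort("`total_bases` must be > 0.")
  }
  trimmed_mean_depth / total_bases * 1e9
}

#' Greedy centroid clustering of contigs into vOTUs
#'
#' Contigs are processed longest first (ties broken lexicographically by
#' id); each contig joins the first already-founded representative to which
#' it shows average nucleotide identity `>= ani_min` and aligned fraction of
#' the shorter sequence `>= af_min`, otherwise it founds a new cluster. The
#' founder — necessarily the longest member — is the representative. The
#' default thresholds (95% ANI over 80% of the shorter contig) are the
#' community standard for viral population (vOTU) delineation.
#'
#' @param contig_lengths Named numeric vector (or tibble with `contig_id`,
#'   `length`) of contig lengths in bp.
#' @param similarities Tibble of pairwise records: `contig_a`, `contig_b`,
#'   `ani_percent` (0–100), `aligned_fraction_shorter` (0–1). Unordered;
#'   records are symmetrized internally, so record order cannot affect the
#'   result.
#' @param ani_min,af_min Inclusive thresholds.
#' @return An object of class `votu_clustering`: tibble `members`
#'   (contig_id, votu_id, representative_id, is_representative) plus the
#'   thresholds.
#' @examples
#' lens <- c(A = 10000, B = 8000, C = 6000)
#' sim <- tibble::tibble(contig_a = c("A", "B"), contig_b = c("B", "C"),
#'                       ani_percent = c(97, 96),
#'                       aligned_fraction_shorter = c(0.9, 0.85))
#' cluster_votus(lens, sim)
#' @export
cluster_votus <- function(contig_lengths, similarities,
                          ani_min = 95, af_min = 0.80) {
  if (is.data.frame(contig_lengths)) {
    contig_lengths <- setNames(contig_lengths$length, contig_lengths$contig_id)
  }
  ids <- names(contig_lengths)
  if (is.null(ids) || anyDuplicated(ids)) {
    abort("`contig_lengths` must be uniquely named by contig id.")
  }
  if (nrow(similarities) > 0) {
    unknown <- setdiff(unique(c(similarities$contig_a, similarities$contig_b)), ids)
    if (length(unknown) > 0) {
      abort(sprintf("similarity record references unknown contig(s): %s",
                    paste(unknown, collapse = ", ")))
    }
  }
  # symmetric lookup of passing pairs
  pass <- similarities[similarities$ani_percent >= ani_min &
                         similarities$aligned_fraction_shorter >= af_min, ,
                       drop = FALSE]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  pass_keys <- unique(key(pass$contig_a, pass$contig_b))

  ord <- ids[order(-contig_lengths[ids], ids)]
  reps <- character(0)
  assignment <- setNames(character(length(ord)), ord)
  for (cid in ord) {
    hit <- NA_character_
    for (r in reps) {
      if (key(cid, r) %in% pass_keys) { hit <- r; break }
    }
    if (is.na(hit)) {
      reps <- c(reps, cid)
      assignment[cid] <- cid
    } else {
      assignment[cid] <- hit
    }
  }
  rep_rank <- setNames(seq_along(reps), reps)
  members <- tibble::tibble(
    contig_id = names(assignment),
    representative_id = unname(assignment),
    votu_id = sprintf("vOTU_%05d", rep_rank[unname(assignment)]),
    is_representative = names(assignment) == unname(assignment)
  )
  members <- dplyr::arrange(members, .data$votu_id, dplyr::desc(.data$is_representative),
                            .data$contig_id)
  structure(list(members = members, ani_min = ani_min, af_min = af_min),
            class = "votu_clustering")
}

#' @export
print.votu_clustering <- function(x, ...) {
  cat(sprintf("<votu_clustering> %d contigs in %d vOTUs (ANI >= %g%%, AF >= %g)\n",
              nrow(x$members), sum(x$members$is_representative),
              x$ani_min, x$af_min))
  print(head(x$members, 10))
  invisible(x)
}

#' @export
tidy.votu_clustering <- function(x, ...) x$members

#' @export
glance.votu_clustering <- function(x, ...) {
  tibble::tibble(n_contigs = nrow(x$members),
                 n_votus = sum(x$members$is_representative),
                 ani_min = x$ani_min, af_min = x$af_min)
}

#' Build the normalized vOTU abundance matrix
#'
#' Assembles, from per-representative coverage summaries, the vOTU x sample
#' matrix of breadth-filtered, per-gigabase-normalized relative abundances.
#' Samples are ordered by metadata date, then id; coverage rows missing for
#' a representative/sample combination count as undetected (zero). Input
#' row order cannot affect the result.
#'
#' @param coverage Tibble with `contig_id`, `sample_id`,
#'   `trimmed_mean_depth`, `breadth`.
#' @param clustering A [cluster_votus()] result (or `NULL` to treat every
#'   contig in `coverage` as its own representative).
#' @param metadata Tibble with `sample_id`, `date`, `total_bases`.
#' @param breadth_min Detection threshold passed to
#'   [apply_detection_filter()].
#' @return A numeric matrix, vOTUs in rows (named by representative id),
#'   samples in columns.
#' @export
build_abundance_matrix <- function(coverage, clustering = NULL, metadata,
                                   breadth_min = 0.70) {
  need <- c("sample_id", "date", "total_bases")
  if (!all(need %in% names(metadata))) {
    abort("`metadata` needs columns sample_id, date, total_bases.")
  }
  if (anyNA(metadata$total_bases)) abort("missing `total_bases` in metadata.")
  samples <- metadata$sample_id[order(metadata$date, metadata$sample_id)]
  if (!all(coverage$sample_id %in% samples)) {
    abort("coverage refers to samples absent from `metadata`.")
  }
  reps <- if (is.null(clustering)) sort(unique(coverage$contig_id)) else
    sort(unique(clustering$members$representative_id))
  cov <- apply_detection_filter(coverage, breadth_min)
  cov <- cov[cov$contig_id %in% reps, , drop = FALSE]
  tb <- setNames(metadata$total_bases, metadata$sample_id)
  mat <- matrix(0, nrow = length(reps), ncol = length(samples),
                dimnames = list(reps, samples))
  if (nrow(cov) > 0) {
    idx <- cbind(match(cov$contig_id, reps), match(cov$sample_id, samples))
    mat[idx] <- normalize_per_gigabase(cov$trimmed_mean_depth,
                                       tb[cov$sample_id])
  }
  mat
}
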