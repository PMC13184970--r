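# Alpha diversity, the centered log-ratio transform, and the univariate
# statistical battery (Wilcoxon families, FDR, Friedman + Kendall's W).

#' Per-sample alpha diversity of a vOTU abundance matrix
#'
#' Computes observed richness S (vOTUs with abundance > 0), richness per
#' gigabase of quality-trimmed reads (S divided by `total_bases`/1e9),
#' Shannon diversity H in natural-log units, Pielou's evenness J = H/ln(S)
#' (undefined, hence `NA`, for S < 2) and the mean abundance per sample.
#'
#' @param x vOTU x sample abundance matrix.
#' @param metadata Tibble with `sample_id` and `total_bases`.
#' @return A tibble, one row per sample.
#' @examples
#' m <- matrix(c(1, 1, 1, 1), 4, 1, dimnames = list(paste0("v", 1:4), "s1"))
#' alpha_diversity(m, tibble::tibble(sample_id = "s1", total_bases = 2e9))
#' @export
alpha_diversity <- function(x, metadata) {
  check_abundance_matrix(x)
  if (!all(c("sample_id", "total_bases") %in% names(metadata))) {
    abort("`metadata` needs columns sample_id and total_bases.")
  }
  if (!all(colnames(x) %in% metadata$sample_id)) {
    abort("every sample column needs a metadata row.")
  }
  tb <- setNames(metadata$total_bases, metadata$sample_id)
  purrr::map_dfr(colnames(x), function(s) {
    v <- x[, s]
    pos <- v[v > 0]
    s_obs <- length(pos)
    h <- if (s_obs == 0) 0 else {
      p <- pos / sum(pos)
      -sum(p * log(p))
    }
    tibble::tibble(
      sample_id = s,
      richness = s_obs,
      richness_per_gb = s_obs / (tb[[s]] / 1e9),
      shannon = h,
      pielou = if (s_obs >= 2) h / log(s_obs) else NA_real_,
      mean_abundance = mean(v)
    )
  })
}

#' Centered log-ratio transform with a pseudo-count
#'
#' Adds `pseudo_count` to every abundance (the zero-inflated per-gigabase
#' abundances make a pseudo-count necessary), then per sample subtracts the
#' mean log from each log abundance. Every sample's CLR values sum to zero.
#'
#' @param x vOTU x sample abundance matrix (non-negative).
#' @param pseudo_count Positive offset added before the log (default 0.001).
#' @return Matrix of the same shape, class `"clr_matrix"` with the
#'   pseudo-count recorded as attribute `pseudo_count`.
#' @examples
#' m <- matrix(c(0, 0.999), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' clr_transform(m)  # ~ -3.4539, +3.4539
#' @export
clr_transform <- function(x, pseudo_count = 0.001) {
  check_abundance_matrix(x)
  if (pseudo_count <= 0 && any(x == 0)) {
    abort("`pseudo_count` must be > 0 when zeros are present.")
  }
  lx <- log(x + pseudo_count)
  clr <- sweep(lx, 2, colMeans(lx))
  attr(clr, "pseudo_count") <- pseudo_count
  class(clr) <- c("clr_matrix", class(clr))
  clr
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration for small untied samples (both groups at most 25),
#' otherwise the normal approximation with tie and continuity correction.
#' The effect size reported is the difference of group medians (a - b).
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A one-row result tibble (method, statistic, df, p, p_adjusted,
#'   effect_size, note).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))  # exact p = 0.1
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("each group needs n >= 2.")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) <= 25 && length(b) <= 25
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE, alternative = "two.sided"))
  test_result(
    method = if (exact) "wilcoxon_rank_sum_exact" else "wilcoxon_rank_sum_normal",
    statistic = unname(wt$statistic), p = wt$p.value,
    effect_size = median(a) - median(b)
  )
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped per the Wilcoxon convention; if every
#' difference is zero the test is vacuous and p = 1 is returned with a
#' warning and a note flag.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return A one-row result tibble.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must be paired (equal length).")
  d <- a - b
  if (all(d == 0)) {
    warn("all paired differences are zero; test is vacuous (p = 1).")
    return(test_result("wilcoxon_signed_rank", statistic = NA_real_, p = 1,
                       effect_size = 0, note = "all differences zero"))
  }
  nz <- d[d != 0]
  ties <- anyDuplicated(abs(nz)) > 0
  exact <- !ties && length(nz) <= 25
  wt <- suppressWarnings(
    wilcox.test(a, b, paired = TRUE, exact = exact, correct = TRUE))
  test_result(
    method = if (exact) "wilcoxon_signed_rank_exact" else "wilcoxon_signed_rank_normal",
    statistic = unname(wt$statistic), p = wt$p.value,
    effect_size = median(d)
  )
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement; the input order is
#' preserved and values never exceed 1.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
adjust_fdr <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort("`p` must be p-values in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Friedman test across timepoints with Kendall's W effect size
#'
#' Rows of `x` are the repeatedly measured subjects (vOTUs), columns the
#' treatments (timepoints). Within-subject mid-ranks feed the tie-corrected
#' chi-squared statistic with df = k - 1; Kendall's W = chi-squared /
#' (n (k - 1)) measures concordance. A fully tied matrix (every subject
#' constant) yields chi-squared = 0, W = 0, p = 1.
#'
#' @param x Numeric matrix, subjects x treatments, no missing cells.
#' @return A one-row result tibble; `effect_size` is Kendall's W, `df` is
#'   k - 1.
#' @examples
#' kendalls_w(5543.6, n = 22534, k = 14)  # ~0.019
#' @export
friedman_kendall <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) abort("need >= 2 subjects and >= 2 treatments.")
  if (anyNA(x)) abort("missing cells are not allowed (no imputation).")
  ft <- friedman.test(x)
  chisq <- unname(ft$statistic)
  p <- ft$p.value
  if (is.nan(chisq)) { # every block fully tied: no rank variation at all
    chisq <- 0
    p <- 1
  }
  test_result("friedman", statistic = chisq, df = ncol(x) - 1, p = p,
              effect_size = kendalls_w(chisq, nrow(x), ncol(x)))
}

#' @rdname friedman_kendall
#' @param chisq Friedman chi-squared statistic.
#' @param n Number of subjects (vOTUs).
#' @param k Number of treatments (timepoints).
#' @export
kendalls_w <- function(chisq, n, k) {
  chisq / (n * (k - 1))
}

#' Signed-rank comparisons of consecutive timepoints
#'
#' The post hoc companion of [friedman_kendall()]: paired Wilcoxon
#' signed-rank tests across subjects for each consecutive pair of
#' timepoints, FDR-adjusted over the k - 1 pairs.
#'
#' @param x Numeric matrix, subjects x timepoints.
#' @return A tibble with one row per consecutive pair.
#' @export
consecutive_timepoint_tests <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) abort("need >= 2 timepoints.")
  res <- purrr::map_dfr(seq_len(ncol(x) - 1), function(j) {
    r <- wilcoxon_signed_rank(x[, j], x[, j + 1])
    r$pair <- paste(colnames(x)[j], colnames(x)[j + 1], sep = " vs ")
    r
  })
  res$p_adjusted <- adjust_fdr(res$p)
  dplyr::relocate(res, "pair")
}
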