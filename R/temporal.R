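# Temporal structure: log-transformed Bray-Curtis distance decay, its
# partition into balanced-variation and abundance-gradient components,
# month arithmetic, and occupancy-based dynamic classes.

#' Bray-Curtis dissimilarity on log(x + 1) abundances
#'
#' Transforms both abundance vectors with `log1p` and computes
#' `sum(|u - v|) / sum(u + v)`.
#'
#' @param x,y Equal-length non-negative abundance vectors.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis_log <- function(x, y) {
  baselga_partition(x, y)$d_bray
}

#' Baselga partition of Bray-Curtis dissimilarity
#'
#' Splits the (optionally log1p-transformed) Bray-Curtis dissimilarity into
#' a balanced-variation component (substitution of abundance between vOTUs,
#' the abundance analogue of turnover) and an abundance-gradient component
#' (uniform gain/loss). With A = sum of elementwise minima, B and C the
#' group-specific surpluses: d_bray = (B + C)/(2A + B + C), d_balanced =
#' min(B, C)/(A + min(B, C)), d_gradient = d_bray - d_balanced. The three
#' components satisfy d_balanced + d_gradient = d_bray exactly.
#'
#' @param x,y Equal-length non-negative abundance vectors.
#' @param pre_transform Transform applied to both vectors first
#'   (default `log1p`; use `identity` for raw abundances).
#' @return A one-row tibble: d_balanced, d_gradient, d_bray.
#' @examples
#' baselga_partition(c(1, 0), c(0, 1), pre_transform = identity)
#' @export
baselga_partition <- function(x, y, pre_transform = log1p) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (any(x < 0) || any(y < 0)) abort("abundances must be non-negative.")
  u <- pre_transform(x)
  v <- pre_transform(y)
  if (sum(u) + sum(v) == 0) {
    abort("both vectors are all-zero; dissimilarity is undefined.")
  }
  mn <- pmin(u, v)
  a <- sum(mn)
  b <- sum(u - mn)
  c_ <- sum(v - mn)
  d_bray <- (b + c_) / (2 * a + b + c_)
  # min(B, C) = 0 means no substitution at all (one community nested in the
  # other): the balanced component is 0 even when A = 0
  d_bal <- if (min(b, c_) == 0) 0 else min(b, c_) / (a + min(b, c_))
  tibble::tibble(d_balanced = d_bal, d_gradient = d_bray - d_bal,
                 d_bray = d_bray)
}

#' Whole-month difference between two dates
#'
#' `|12 (year_i - year_j) + (month_i - month_j)|`; days are ignored, so
#' first-of-month sampling dates give exact month counts.
#'
#' @param date_i,date_j `Date` vectors (recycled).
#' @return Integer month differences.
#' @examples
#' months_apart(as.Date("2019-10-01"), as.Date("2020-01-01"))  # 3
#' @export
months_apart <- function(date_i, date_j) {
  di <- as.POSIXlt(date_i)
  dj <- as.POSIXlt(date_j)
  abs(12L * (di$year - dj$year) + (di$mon - dj$mon))
}

#' Pairwise temporal distance decay of a community time series
#'
#' For every pair of samples, computes the log1p Bray-Curtis dissimilarity,
#' its Baselga components, and the month difference between sampling dates;
#' optionally runs a Mantel test of a chosen component against the
#' month-distance matrix.
#'
#' @param x vOTU x sample abundance matrix.
#' @param metadata Tibble with `sample_id` and `date`.
#' @param component Dissimilarity tested against time: `"d_balanced"`
#'   (default, the turnover component), `"d_bray"` or `"d_gradient"`.
#' @param n_perm Mantel permutations (default 999); `0` skips the test.
#' @param seed Integer seed for the Mantel permutations.
#' @return A list of class `distance_decay`: `pairs` (tibble of pairwise
#'   rows) and `mantel` (one-row result tibble or `NULL`).
#' @export
distance_decay <- function(x, metadata, component = c("d_balanced", "d_bray",
                                                      "d_gradient"),
                           n_perm = 999, seed = NULL) {
  component <- match.arg(component)
  check_abundance_matrix(x)
  if (!all(colnames(x) %in% metadata$sample_id)) {
    abort("every sample column needs a metadata row with a date.")
  }
  dates <- setNames(metadata$date, metadata$sample_id)[colnames(x)]
  samples <- colnames(x)
  n <- length(samples)
  idx <- utils::combn(n, 2)
  pairs <- purrr::map_dfr(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    part <- baselga_partition(x[, i], x[, j])
    tibble::tibble(sample_i = samples[i], sample_j = samples[j],
                   months_apart = months_apart(dates[i], dates[j]),
                   d_bray = part$d_bray, d_balanced = part$d_balanced,
                   d_gradient = part$d_gradient)
  })
  mantel <- NULL
  if (n_perm > 0) {
    dd <- matrix(0, n, n, dimnames = list(samples, samples))
    dt <- dd
    dd[cbind(idx[1, ], idx[2, ])] <- pairs[[component]]
    dt[cbind(idx[1, ], idx[2, ])] <- pairs$months_apart
    dd <- dd + t(dd)
    dt <- dt + t(dt)
    mantel <- mantel_test(dd, dt, n_perm = n_perm, seed = seed)
  }
  structure(list(pairs = pairs, mantel = mantel, component = component),
            class = "distance_decay")
}

#' @export
print.distance_decay <- function(x, ...) {
  cat(sprintf("<distance_decay> %d sample pairs\n", nrow(x$pairs)))
  if (!is.null(x$mantel)) {
    cat(sprintf("  Mantel (%s vs months): rho = %.3f, p = %.4g\n",
                x$component, x$mantel$statistic, x$mantel$p))
  }
  invisible(x)
}

#' @export
tidy.distance_decay <- function(x, ...) x$pairs

#' @export
glance.distance_decay <- function(x, ...) {
  if (is.null(x$mantel)) return(tibble::tibble(n_pairs = nrow(x$pairs)))
  tibble::tibble(n_pairs = nrow(x$pairs), component = x$component,
                 mantel_rho = x$mantel$statistic, mantel_p = x$mantel$p)
}

#' Occupancy-based dynamic classes of vOTUs
#'
#' Classifies each vOTU by its detection occupancy f = detections /
#' timepoints: sporadic if 0 < f < 0.25, intermittent if 0.25 <= f <= 0.75,
#' persistent if f > 0.75. At 14 timepoints these thresholds give the
#' integer bins 1-3, 4-10 and 11-14. vOTUs never detected are excluded.
#'
#' @param x vOTU x timepoint abundance (or logical detection) matrix;
#'   detection is abundance > 0.
#' @return A tibble: votu_id, n_detections, n_timepoints, occupancy, class.
#' @export
classify_dynamics <- function(x) {
  if (!is.matrix(x)) abort("`x` must be a vOTU x timepoint matrix.")
  det <- x > 0
  n_t <- ncol(det)
  if (n_t < 1) abort("need >= 1 timepoint.")
  n_det <- rowSums(det)
  keep <- n_det > 0
  f <- n_det[keep] / n_t
  tibble::tibble(
    votu_id = rownames(det)[keep],
    n_detections = as.integer(n_det[keep]),
    n_timepoints = n_t,
    occupancy = f,
    class = dplyr::case_when(
      f > 0.75 ~ "persistent",
      f >= 0.25 ~ "intermittent",
      TRUE ~ "sporadic"
    )
  )
}

#' Per-timepoint percentages of the dynamic classes
#'
#' At each timepoint, among the vOTUs detected there, the percentage
#' belonging to each dynamic class; percentages sum to 100 per timepoint.
#' Timepoints with no detections are omitted with a warning.
#'
#' @param x vOTU x timepoint abundance matrix.
#' @param classification Result of [classify_dynamics()] on the same
#'   matrix (computed if missing).
#' @return A tibble: timepoint, class, percent, n_detected.
#' @export
dynamics_fractions <- function(x, classification = NULL) {
  if (is.null(classification)) classification <- classify_dynamics(x)
  det <- x > 0
  cls <- setNames(classification$class, classification$votu_id)
  out <- purrr::map_dfr(seq_len(ncol(det)), function(t) {
    ids <- rownames(det)[det[, t]]
    if (length(ids) == 0) return(NULL)
    counts <- table(factor(cls[ids],
                           levels = c("sporadic", "intermittent", "persistent")))
    tibble::tibble(timepoint = colnames(det)[t] %||% as.character(t),
                   class = names(counts),
                   percent = 100 * as.numeric(counts) / length(ids),
                   n_detected = length(ids))
  })
  empty <- sum(colSums(det) == 0)
  if (empty > 0) {
    warn(sprintf("%d timepoint(s) with zero detections omitted.", empty))
  }
  out
}
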