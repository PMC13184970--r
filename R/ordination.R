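# Aitchison geometry: distances between samples, principal coordinates,
# and silhouette-guided k-means on the ordination.

#' Aitchison distance between samples
#'
#' Euclidean distance between the CLR vectors of each pair of samples —
#' the standard metric for compositional community data.
#'
#' @param clr A CLR-transformed matrix ([clr_transform()]), vOTUs x samples.
#' @return A `dist` object over samples.
#' @export
aitchison_distance <- function(clr) {
  if (!is.matrix(clr) || !is.numeric(clr)) abort("`clr` must be a numeric matrix.")
  if (ncol(clr) < 2) abort("need at least 2 samples.")
  dist(t(clr), method = "euclidean")
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric scaling: double-centering of -0.5 d^2, eigendecomposition,
#' coordinates = eigenvectors scaled by sqrt(eigenvalue) for positive
#' eigenvalues; the percent variance per axis is computed over the positive
#' eigenvalues only.
#'
#' @param d A `dist` object or symmetric zero-diagonal matrix.
#' @return An object of class `pcoa_ordination`: `coordinates`
#'   (samples x axes), `eigenvalues`, `percent_variance`.
#' @export
pcoa_ordination <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-12)) abort("`d` must be symmetric.")
  if (any(abs(diag(m)) > 1e-12)) abort("`d` must have a zero diagonal.")
  n <- nrow(m)
  if (n < 2) abort("need at least 2 samples.")
  fit <- suppressWarnings(cmdscale(stats::as.dist(m), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(eig))
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_along(pos))
  rownames(coords) <- rownames(m)
  structure(list(
    coordinates = coords,
    eigenvalues = eig,
    percent_variance = 100 * eig[pos] / sum(eig[pos])
  ), class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("<pcoa_ordination> %d samples, %d positive axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat(sprintf("  variance explained: %s ...\n",
              paste0(round(head(x$percent_variance, 3), 1), "%", collapse = ", ")))
  invisible(x)
}

#' @export
tidy.pcoa_ordination <- function(x, ...) {
  out <- tibble::as_tibble(x$coordinates, rownames = "sample_id")
  out
}

#' @export
glance.pcoa_ordination <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$coordinates),
    n_axes = ncol(x$coordinates),
    pct_axis1 = x$percent_variance[1],
    pct_axis2 = if (length(x$percent_variance) >= 2) x$percent_variance[2] else NA_real_
  )
}

#' Choose k for k-means by silhouette width
#'
#' For each candidate k, runs k-means with `n_restarts` restarts on the
#' ordination coordinates and scores the mean silhouette width (Euclidean
#' distance); returns the smallest k attaining the maximal width, per the
#' "lowest k yielding the highest silhouette" rule.
#'
#' @param ordination A [pcoa_ordination()] result (or a coordinate matrix).
#' @param k_min,k_max Candidate range; `k_max` defaults to
#'   `min(8, n - 1)`.
#' @param n_restarts k-means restarts per k (default 100).
#' @param seed Integer seed for the k-means initializations.
#' @param axes `"all"` (default) uses every positive-eigenvalue axis,
#'   preserving the full Aitchison geometry; `"first2"` restricts to the
#'   plotted plane.
#' @return A list of class `k_selection`: `k`, `labels` (named cluster
#'   vector), and a tibble `silhouette` of mean widths per candidate k.
#' @export
select_k_silhouette <- function(ordination, k_min = 2L, k_max = NULL,
                                n_restarts = 100L, seed = 1L,
                                axes = c("all", "first2")) {
  axes <- match.arg(axes)
  coords <- if (inherits(ordination, "pcoa_ordination"))
    ordination$coordinates else as.matrix(ordination)
  if (axes == "first2") coords <- coords[, seq_len(min(2, ncol(coords))), drop = FALSE]
  n <- nrow(coords)
  if (n < 3) abort("need at least 3 samples to cluster.")
  if (is.null(k_max)) k_max <- min(8L, n - 1L)
  k_max <- min(k_max, n - 1L)
  d <- dist(coords)
  with_seed_scope(seed, {
    rows <- purrr::map_dfr(seq.int(k_min, k_max), function(k) {
      km <- kmeans(coords, centers = k, nstart = n_restarts, iter.max = 50)
      sil <- cluster::silhouette(km$cluster, d)
      tibble::tibble(k = k, mean_silhouette = mean(sil[, "sil_width"]),
                     labels = list(setNames(km$cluster, rownames(coords))))
    })
    best <- rows$k[which.max(rows$mean_silhouette)] # first max = smallest k
    structure(list(
      k = best,
      labels = rows$labels[[match(best, rows$k)]],
      silhouette = rows[, c("k", "mean_silhouette")]
    ), class = "k_selection")
  })
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> k = %d (mean silhouette %.3f)\n", x$k,
              max(x$silhouette$mean_silhouette)))
  invisible(x)
}

#' @export
tidy.k_selection <- function(x, ...) x$silhouette

#' @export
glance.k_selection <- function(x, ...) {
  tibble::tibble(k = x$k,
                 mean_silhouette = max(x$silhouette$mean_silhouette))
}
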