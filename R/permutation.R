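# Permutation statistics on distance matrices: PERMANOVA (global and
# pairwise), environmental vector fitting, and the Mantel test. All
# permutation p-values use the add-one convention (b + 1) / (m + 1), whose
# floor at 999 permutations is 0.001.

perm_p <- function(exceed, n_perm) (exceed + 1) / (n_perm + 1)

# canonical signature of the partition a label vector induces (label names
# do not matter, the grouping of sample indices does)
partition_signature <- function(labels) {
  paste(sort(vapply(split(seq_along(labels), labels),
                    paste, character(1), collapse = ",")),
        collapse = ";")
}

# sum of squares within groups from a squared-distance matrix
ss_within <- function(d2, labels) {
  s <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    s <- s + sum(d2[idx, idx]) / (2 * length(idx))
  }
  s
}

#' Permutational multivariate analysis of variance
#'
#' One-factor PERMANOVA on a distance matrix: total sum of squares from the
#' Gower-centered squared distances, within-group sum of squares from
#' group-blocked centering, pseudo-F with (g - 1, n - g) degrees of freedom
#' and r-squared = SS_between / SS_total. Significance by permutation of
#' the group labels, p = (#{F_perm >= F_obs} + 1) / (n_perm + 1).
#'
#' @param d A `dist` or symmetric matrix over samples.
#' @param labels Group label per sample (>= 2 groups, each with >= 2
#'   samples).
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed for the permutations (`NULL` = unseeded).
#' @return A one-row result tibble; `statistic` is the pseudo-F, `df` the
#'   numerator df (g - 1), `effect_size` the r-squared.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = NULL) {
  m <- as.matrix(d)
  n <- nrow(m)
  labels <- as.character(labels)
  if (length(labels) != n) abort("`labels` must have one entry per sample.")
  sizes <- table(labels)
  if (length(sizes) < 2) abort("need >= 2 groups.")
  if (any(sizes < 2)) abort("every group needs >= 2 samples.")
  d2 <- m^2
  ss_total <- sum(d2) / (2 * n)
  g <- length(sizes)
  f_of <- function(lab) {
    ssw <- ss_within(d2, lab)
    ssb <- ss_total - ssw
    (ssb / (g - 1)) / (ssw / (n - g))
  }
  ssw_obs <- ss_within(d2, labels)
  ssb_obs <- ss_total - ssw_obs
  f_obs <- (ssb_obs / (g - 1)) / (ssw_obs / (n - g))
  r2 <- ssb_obs / ss_total
  # the observed labeling is already the +1 of the add-one convention, so a
  # drawn permutation that merely reproduces the observed partition of the
  # samples (e.g. a relabeling of the same groups) is redrawn
  sig <- partition_signature(labels)
  exceed <- with_seed_scope(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      perm <- sample(labels)
      tries <- 0L
      while (partition_signature(perm) == sig && tries < 100L) {
        perm <- sample(labels)
        tries <- tries + 1L
      }
      f_of(perm) >= f_obs
    }, logical(1)))
  })
  test_result("permanova", statistic = f_obs, df = g - 1,
              p = perm_p(exceed, n_perm), effect_size = r2)
}

#' Pairwise PERMANOVA with FDR correction
#'
#' Runs [permanova()] on the sub-distance-matrix of every pair of groups
#' and adjusts the p-values with Benjamini-Hochberg across pairs.
#'
#' @inheritParams permanova
#' @return A tibble with one row per group pair (columns `group_a`,
#'   `group_b` plus the result columns).
#' @export
pairwise_permanova <- function(d, labels, n_perm = 999, seed = NULL) {
  m <- as.matrix(d)
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2) abort("need >= 2 groups.")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  seeds <- if (is.null(seed)) vector("list", length(pairs)) else
    as.list(seed + seq_along(pairs))
  res <- purrr::map2_dfr(pairs, seeds, function(pr, s) {
    idx <- labels %in% pr
    r <- permanova(m[idx, idx, drop = FALSE], labels[idx], n_perm, s)
    dplyr::bind_cols(tibble::tibble(group_a = pr[1], group_b = pr[2]), r)
  })
  res$p_adjusted <- adjust_fdr(res$p)
  res
}

#' Fit environmental vectors onto an ordination
#'
#' Regresses each (centered) environmental variable on the first two
#' ordination axes; the fit's coefficient of determination is the r-squared
#' and the normalized coefficient vector gives the arrow direction.
#' Significance by permuting the variable across samples,
#' p = (#{r2_perm >= r2_obs} + 1) / (n_perm + 1). Samples with missing
#' values are dropped per variable with a warning; constant variables are
#' flagged and excluded from testing.
#'
#' @param ordination A [pcoa_ordination()] result or coordinate matrix
#'   (first two axes are used).
#' @param env Data frame of environmental variables, rows aligned with the
#'   ordination samples (a `sample_id` column, if present, is used to
#'   align).
#' @param n_perm Permutations (default 999).
#' @param seed Integer seed.
#' @return A tibble: variable, axis1, axis2 (direction cosines),
#'   r_squared, p, note.
#' @export
envfit_vectors <- function(ordination, env, n_perm = 999, seed = NULL) {
  coords <- if (inherits(ordination, "pcoa_ordination"))
    ordination$coordinates else as.matrix(ordination)
  if (ncol(coords) < 2) abort("ordination needs at least 2 axes.")
  x_all <- coords[, 1:2, drop = FALSE]
  env <- as.data.frame(env)
  if ("sample_id" %in% names(env)) {
    if (!is.null(rownames(x_all)) && all(rownames(x_all) %in% env$sample_id)) {
      env <- env[match(rownames(x_all), env$sample_id), , drop = FALSE]
    }
    env$sample_id <- NULL
  }
  env <- env[vapply(env, is.numeric, logical(1))]
  if (nrow(env) != nrow(x_all)) abort("`env` rows must match the samples.")

  seeds <- if (is.null(seed)) vector("list", ncol(env)) else
    as.list(seed + seq_len(ncol(env)))
  purrr::map2_dfr(names(env), seeds, function(v, s) {
    y <- env[[v]]
    keep <- !is.na(y)
    if (!all(keep)) {
      warn(sprintf("dropping %d sample(s) with missing `%s`.", sum(!keep), v))
    }
    yk <- y[keep]
    if (length(unique(yk)) < 2) {
      return(tibble::tibble(variable = v, axis1 = NA_real_, axis2 = NA_real_,
                            r_squared = NA_real_, p = NA_real_,
                            note = "constant variable; excluded"))
    }
    x <- scale(x_all[keep, , drop = FALSE], scale = FALSE)
    qr_x <- qr(x)
    r2_of <- function(yv) {
      yc <- yv - mean(yv)
      fit <- qr.fitted(qr_x, yc)
      sum(fit^2) / sum(yc^2)
    }
    r2_obs <- r2_of(yk)
    beta <- qr.coef(qr_x, yk - mean(yk))
    dir <- beta / sqrt(sum(beta^2))
    exceed <- with_seed_scope(s, {
      sum(vapply(seq_len(n_perm),
                 function(i) r2_of(sample(yk)) >= r2_obs, logical(1)))
    })
    tibble::tibble(variable = v, axis1 = unname(dir[1]), axis2 = unname(dir[2]),
                   r_squared = r2_obs, p = perm_p(exceed, n_perm),
                   note = NA_character_)
  })
}

#' Mantel test between two distance matrices
#'
#' Correlates the upper-triangle entries of `d1` and `d2` (Spearman by
#' default) and assesses significance by jointly permuting the rows and
#' columns of `d2`; one-sided (positive association), add-one convention.
#'
#' @param d1,d2 `dist` objects or symmetric matrices over the same samples.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm Permutations (default 999).
#' @param seed Integer seed.
#' @return A one-row result tibble; `statistic` is the correlation.
#' @export
mantel_test <- function(d1, d2, method = c("spearman", "pearson"),
                        n_perm = 999, seed = NULL) {
  method <- match.arg(method)
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  n <- nrow(m1)
  if (!all(dim(m1) == dim(m2))) abort("`d1` and `d2` must match in size.")
  if (n < 4) abort("need >= 4 samples for a meaningful permutation test.")
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  r_obs <- cor(v1, m2[ut], method = method)
  exceed <- with_seed_scope(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      cor(v1, m2[p, p][ut], method = method) >= r_obs
    }, logical(1)))
  })
  test_result(paste0("mantel_", method), statistic = r_obs,
              p = perm_p(exceed, n_perm))
}
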