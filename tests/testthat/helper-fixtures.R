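# Fixtures built in code, plus independent oracles used across test files.

`%||%` <- function(x, y) if (is.null(x)) y else x

toy_matrix <- function(values, votus = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- votus %||% paste0("v", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  m
}

toy_metadata <- function(samples, total_bases = 1e9,
                         ecosystem = "lagoon",
                         start = as.Date("2019-10-01")) {
  tibble::tibble(
    sample_id = samples,
    ecosystem = rep_len(ecosystem, length(samples)),
    date = seq(start, by = "month", length.out = length(samples)),
    total_bases = rep_len(total_bases, length(samples))
  )
}

# independent oracle for the greedy centroid rule: a literal, unoptimized
# re-statement used to cross-check cluster_votus()
oracle_centroid_clusters <- function(lengths, sims, ani_min = 95, af_min = 0.80) {
  ids <- names(lengths)
  ord <- ids[order(-lengths[ids], ids)]
  passes <- function(a, b) {
    hit <- (sims$contig_a == a & sims$contig_b == b) |
      (sims$contig_a == b & sims$contig_b == a)
    any(hit & sims$ani_percent >= ani_min &
          sims$aligned_fraction_shorter >= af_min)
  }
  reps <- character(0)
  assign <- character(0)
  for (cid in ord) {
    joined <- FALSE
    for (r in reps) {
      if (passes(cid, r)) {
        assign[cid] <- r
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, cid)
      assign[cid] <- cid
    }
  }
  assign
}

random_clustering_instance <- function(n_max = 10) {
  n <- sample(2:n_max, 1)
  ids <- sample(LETTERS, n)
  lengths <- setNames(sample(1000:20000, n), ids)
  pairs <- t(utils::combn(ids, 2))
  keep <- runif(nrow(pairs)) < 0.5
  tibble::tibble(
    contig_a = pairs[keep, 1],
    contig_b = pairs[keep, 2],
    ani_percent = runif(sum(keep), 90, 100),
    aligned_fraction_shorter = runif(sum(keep), 0.6, 1)
  ) -> sims
  list(lengths = lengths, sims = sims)
}
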