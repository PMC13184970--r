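# Synthetic datasets with planted, recoverable structure. Everything is
# drawn inside a seeded scope: the same config regenerates bit-identical
# output and the caller's random state is never touched.

first_of_month_seq <- function(n, start = as.Date("2019-10-01")) {
  seq(start, by = "month", length.out = n)
}

# occupancy bins implied by the class thresholds (<0.25 / [0.25,0.75] / >0.75)
occupancy_bins <- function(n_timepoints) {
  t <- n_timepoints
  i_lo <- as.integer(ceiling(0.25 * t))      # first intermittent count
  i_hi <- as.integer(floor(0.75 * t))        # last intermittent count
  list(
    sporadic = if (i_lo >= 2L) seq_len(i_lo - 1L) else integer(0),
    intermittent = seq.int(i_lo, i_hi),
    persistent = seq.int(i_hi + 1L, t)
  )
}

#' Simulate a two-ecosystem vOTU dataset
#'
#' Draws a vOTU x sample abundance matrix for a lagoon and an open-sea group
#' that differ in richness (`n_votus_lagoon` vs `n_votus_sea`), in mean
#' nonzero abundance (`abundance_fold`, applied on the lognormal log scale)
#' and in membership (a `shared_fraction` of sea vOTUs also occurs in the
#' lagoon). Detection is Bernoulli per vOTU x sample; nonzero abundances are
#' lognormal, emulating the zero-inflated per-gigabase abundances of mapped
#' viral populations.
#'
#' @param config A [sim_config()].
#' @return A list with `abundance` (vOTU x sample matrix), `metadata`
#'   (tibble: sample_id, ecosystem, date, total_bases, environmental
#'   columns) and `truth` (tibble votu_id/origin plus the config).
#' @examples
#' sim <- simulate_two_ecosystems(sim_config(seed = 1, n_votus_lagoon = 40,
#'                                           n_votus_sea = 25))
#' dim(sim$abundance)
#' @export
simulate_two_ecosystems <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_scope(config$seed, {
    n_shared <- round(config$shared_fraction * config$n_votus_sea)
    lagoon_ids <- sprintf("vL%05d", seq_len(config$n_votus_lagoon))
    sea_ids <- sprintf("vS%05d", seq_len(config$n_votus_sea))
    shared_ids <- if (n_shared > 0) sample(sea_ids, n_shared) else character(0)
    all_ids <- c(lagoon_ids, sea_ids)

    ns <- config$n_samples_per_group
    samples <- c(sprintf("MM%02d", seq_len(ns)), sprintf("MS%02d", seq_len(ns)))
    eco <- rep(c("lagoon", "open_sea"), each = ns)

    mat <- matrix(0, nrow = length(all_ids), ncol = length(samples),
                  dimnames = list(all_ids, samples))
    mu_lagoon <- config$lognormal_mu + log(config$abundance_fold)
    for (j in seq_along(samples)) {
      pool <- if (eco[j] == "lagoon") c(lagoon_ids, shared_ids) else sea_ids
      det <- pool[runif(length(pool)) < config$detection_prob]
      mu <- if (eco[j] == "lagoon") mu_lagoon else config$lognormal_mu
      mat[det, j] <- rlnorm(length(det), meanlog = mu,
                            sdlog = config$lognormal_sigma)
    }

    metadata <- tibble::tibble(
      sample_id = samples,
      ecosystem = eco,
      date = rep(first_of_month_seq(ns), 2L),
      total_bases = round(runif(length(samples), 5e9, 1e10)),
      temperature = round(20 + 6 * rnorm(length(samples)), 2),
      salinity = round(ifelse(eco == "lagoon", 43, 38) + rnorm(length(samples)), 2)
    )
    origin <- ifelse(all_ids %in% shared_ids, "shared",
                     ifelse(all_ids %in% lagoon_ids, "lagoon", "open_sea"))
    list(
      abundance = mat,
      metadata = metadata,
      truth = list(
        votu_origin = tibble::tibble(votu_id = all_ids, origin = origin),
        config = config
      )
    )
  })
}

#' Simulate a lagoon vOTU time series with planted dynamics
#'
#' Each vOTU is assigned an occupancy class from `occupancy_mixture` and a
#' contiguous run of detections whose length falls in that class's bin, so
#' (i) the occupancy classifier recovers the planted classes exactly and
#' (ii) community composition drifts monotonically in time, planting a
#' distance-decay signal. At each disturbance timepoint an extra cohort of
#' sporadic vOTUs (15% of the base set) is injected. One environmental
#' variable (`iz_percent`) is built as a linear blend of the first
#' principal-coordinate axis of the community (Aitchison geometry) and
#' Gaussian noise, scaled so its planted coefficient of determination
#' against that axis is `env_signal_r2`; the remaining environmental
#' columns are pure noise decoys.
#'
#' @param config A [sim_config()]; needs `n_timepoints >= 4`.
#' @return A list with `abundance`, `metadata` and `truth` (per-vOTU class,
#'   planted driver name, disturbance cohort ids).
#' @examples
#' sim <- simulate_time_series(sim_config(seed = 1, n_votus_lagoon = 60))
#' table(sim$truth$votu_classes$planted_class)
#' @export
simulate_time_series <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  t_n <- config$n_timepoints
  if (t_n < 4L) abort("`n_timepoints` must be >= 4 for a time series.")
  bins <- occupancy_bins(t_n)
  if (length(bins$sporadic) == 0 &&
      (config$occupancy_mixture[["sporadic"]] > 0 ||
       length(config$disturbance_timepoints) > 0)) {
    abort("no attainable sporadic occupancy at this `n_timepoints`.")
  }
  with_seed_scope(config$seed, {
    n <- config$n_votus_lagoon
    ids <- sprintf("vL%05d", seq_len(n))
    classes <- sample(names(config$occupancy_mixture), n, replace = TRUE,
                      prob = config$occupancy_mixture)

    det <- matrix(FALSE, nrow = n, ncol = t_n, dimnames = list(ids, NULL))
    for (i in seq_len(n)) {
      bin <- bins[[classes[i]]]
      n_det <- if (length(bin) == 1L) bin else sample(bin, 1L)
      start <- sample.int(t_n - n_det + 1L, 1L)
      det[i, start:(start + n_det - 1L)] <- TRUE
    }

    # disturbance cohorts: sporadic vOTUs detected only at the event
    extra_ids <- character(0)
    extra_det <- NULL
    for (td in config$disturbance_timepoints) {
      n_extra <- max(1L, round(0.15 * n))
      ide <- sprintf("vD%02d_%04d", td, seq_len(n_extra))
      de <- matrix(FALSE, nrow = n_extra, ncol = t_n, dimnames = list(ide, NULL))
      de[, td] <- TRUE
      extra_ids <- c(extra_ids, ide)
      extra_det <- rbind(extra_det, de)
    }
    det <- rbind(det, extra_det)
    classes <- c(classes, rep("sporadic", length(extra_ids)))
    all_ids <- rownames(det)

    mat <- matrix(0, nrow = nrow(det), ncol = t_n,
                  dimnames = list(all_ids, sprintf("T%02d", seq_len(t_n))))
    n_pos <- sum(det)
    mat[det] <- rlnorm(n_pos, meanlog = config$lognormal_mu,
                       sdlog = config$lognormal_sigma)

    # planted environmental driver: blend of community axis 1 and noise
    clr <- clr_transform(mat)
    ax1 <- pcoa_ordination(aitchison_distance(clr))$coordinates[, 1]
    z1 <- as.numeric(scale(ax1))
    noise <- as.numeric(scale(rnorm(t_n)))
    r2 <- config$env_signal_r2
    iz <- sqrt(r2) * z1 + sqrt(1 - r2) * noise
    metadata <- tibble::tibble(
      sample_id = colnames(mat),
      ecosystem = "lagoon",
      date = first_of_month_seq(t_n),
      total_bases = round(runif(t_n, 5e9, 1e10)),
      iz_percent = round(30 + 12 * iz, 3),
      temperature = round(20 + 6 * rnorm(t_n), 2),
      salinity = round(43 + rnorm(t_n), 2),
      nitrate = round(abs(rnorm(t_n, 2, 1)), 3),
      chlorophyll_a = round(abs(rnorm(t_n, 3, 1.5)), 3)
    )
    list(
      abundance = mat,
      metadata = metadata,
      truth = list(
        votu_classes = tibble::tibble(votu_id = all_ids,
                                      planted_class = classes),
        planted_env_driver_ids = "iz_percent",
        decoy_env_ids = c("temperature", "salinity", "nitrate", "chlorophyll_a"),
        disturbance_cohort_ids = extra_ids,
        config = config
      )
    )
  })
}

#' Simulate per-position coverage profiles
#'
#' Generates a per-contig coverage summary for one sample: each position is
#' covered with probability `breadth`, and covered positions carry either a
#' constant depth or Poisson-distributed depth around `mean_depth`. The
#' per-position vectors are kept (list-column `depth`) so that summary
#' statistics can be recomputed independently.
#'
#' @param lengths Integer vector of contig lengths (bp).
#' @param breadth Target breadth in `[0, 1]`, recycled across contigs.
#' @param mean_depth Mean read depth of covered positions, recycled.
#' @param total_bases Total quality-trimmed bases of the sample.
#' @param seed Integer seed.
#' @param depth_model `"poisson"` (default) or `"constant"`.
#' @param sample_id Sample label for the emitted rows.
#' @param trim Trim fraction used for the summary `trimmed_mean_depth`.
#' @return A tibble: contig_id, sample_id, contig_length, depth (list),
#'   trimmed_mean_depth, breadth, total_bases.
#' @examples
#' cov <- simulate_coverage(lengths = c(1000, 2000), breadth = 0.9,
#'                          mean_depth = 5, seed = 1)
#' @export
simulate_coverage <- function(lengths, breadth = 0.9, mean_depth = 5,
                              total_bases = 1e9, seed = 1L,
                              depth_model = c("poisson", "constant"),
                              sample_id = "S01", trim = 0.05) {
  if (length(lengths) < 1L || any(lengths < 1)) {
    abort("`lengths` must be contig lengths >= 1 bp.")
  }
  depth_model <- match.arg(depth_model)
  n <- length(lengths)
  breadth <- rep_len(breadth, n)
  mean_depth <- rep_len(mean_depth, n)
  with_seed_scope(seed, {
    rows <- purrr::map(seq_len(n), function(i) {
      l <- lengths[i]
      covered <- runif(l) < breadth[i]
      d <- numeric(l)
      if (any(covered)) {
        d[covered] <- if (depth_model == "constant") mean_depth[i] else
          stats::rpois(sum(covered), max(mean_depth[i] - 1, 0)) + 1
      }
      tibble::tibble(
        contig_id = sprintf("contig_%04d", i),
        sample_id = sample_id,
        contig_length = as.integer(l),
        depth = list(d),
        trimmed_mean_depth = trimmed_mean(d, trim),
        breadth = mean(d > 0),
        total_bases = total_bases
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Simulate vOTU annotations with planted group enrichments
#'
#' Emits a vOTU-level annotation table (genome quality tier, host genus,
#' replicative strategy, auxiliary-gene categories) plus the per-contig
#' evidence rows the calls derive from, so the annotation rules
#' ([call_temperate()], [filter_avgs()]) are exercised on generated
#' evidence rather than on pre-made labels. Planted structure: the
#' temperate fraction per ecosystem is `config$temperate_fraction`; the
#' host genus "Vibrio" and the AVG categories "DNA methyltransferase" and
#' "2OG/Fe(II)-dependent oxygenase" are enriched in the lagoon group by
#' `config$enrichment_points` percentage points, while "Pelagibacter" is
#' enriched in the open-sea group by the same amount.
#'
#' @param votu_ids Character vOTU ids.
#' @param config A [sim_config()].
#' @param origin Ecosystem label per vOTU (`"lagoon"`/`"open_sea"`);
#'   defaults to all-lagoon.
#' @return A list with `annotations` (vOTU-level tibble), `avg_genes`
#'   (retained gene rows), `evidence` (per-contig evidence rows) and
#'   `truth` (planted frequencies and enriched categories).
#' @examples
#' ann <- simulate_annotations(sprintf("v%03d", 1:50), sim_config(seed = 1))
#' @export
simulate_annotations <- function(votu_ids, config = sim_config(),
                                 origin = NULL) {
  if (length(votu_ids) < 1L) abort("`votu_ids` must be non-empty.")
  stopifnot(inherits(config, "sim_config"))
  if (is.null(origin)) origin <- rep("lagoon", length(votu_ids))
  if (length(origin) != length(votu_ids) ||
      !all(origin %in% c("lagoon", "open_sea"))) {
    abort("`origin` must be 'lagoon'/'open_sea' per vOTU.")
  }
  ep <- config$enrichment_points / 100
  host_pool <- c("Vibrio", "Pelagibacter", "Synechococcus_C", "Polaribacter",
                 "Aurantivirga", "Actinomarina")
  avg_pool <- c("DNA methyltransferase", "2OG/Fe(II)-dependent oxygenase",
                "heme biosynthesis", "ribosome biogenesis",
                "lipopolysaccharide biosynthesis", "photosynthesis",
                "nucleotide biosynthesis", "polysaccharide biosynthesis")
  lagoon_avg <- avg_pool[1:2]

  with_seed_scope(config$seed + 1L, {
    n <- length(votu_ids)
    tiers <- sample(c("complete", "high", "medium", "low", "not_determined"),
                    n, replace = TRUE, prob = c(0.05, 0.2, 0.3, 0.35, 0.1))

    # hosts: ~30% assigned; Vibrio enriched in lagoon, Pelagibacter at sea
    host <- rep(NA_character_, n)
    has_host <- runif(n) < 0.3
    base_p <- rep(1 / length(host_pool), length(host_pool))
    for (i in which(has_host)) {
      p <- base_p
      if (origin[i] == "lagoon") p[1] <- p[1] + ep else p[2] <- p[2] + ep
      host[i] <- sample(host_pool, 1L, prob = p / sum(p))
    }

    # replicative strategy via evidence rows
    temp_frac <- config$temperate_fraction[origin]
    planted_temperate <- runif(n) < temp_frac
    bitscore <- ifelse(planted_temperate, runif(n, 60, 150), runif(n, 0, 45))
    hq <- tiers %in% c("complete", "high")
    lifestyle <- ifelse(hq & !planted_temperate, "virulent", NA_character_)
    lifestyle_prob <- ifelse(!is.na(lifestyle), runif(n, 0.95, 1), NA_real_)
    evidence <- tibble::tibble(
      contig_id = votu_ids, votu_id = votu_ids, quality_tier = tiers,
      recombinase_bitscore = round(bitscore, 1),
      lifestyle = lifestyle, lifestyle_probability = round(lifestyle_prob, 4)
    )
    strategy <- call_temperate(evidence)

    # AVG genes: Bernoulli per category, lagoon-enriched for two categories;
    # plus decoy rows that the aux-score/flag/bit-score filter must drop
    base_cat_p <- 0.02
    gene_rows <- purrr::map(seq_len(n), function(i) {
      p <- rep(base_cat_p, length(avg_pool))
      if (origin[i] == "lagoon") p[avg_pool %in% lagoon_avg] <- base_cat_p + ep
      carried <- avg_pool[runif(length(avg_pool)) < p]
      if (length(carried) == 0) return(NULL)
      tibble::tibble(
        contig_id = votu_ids[i], votu_id = votu_ids[i],
        gene_id = paste0(votu_ids[i], "_g", seq_along(carried)),
        category = carried,
        bit_score = round(runif(length(carried), 60, 300), 1),
        aux_score = sample(1:3, length(carried), replace = TRUE),
        amg_flags = ""
      )
    })
    genes <- dplyr::bind_rows(gene_rows)
    n_decoy <- max(1L, round(0.05 * n))
    decoys <- tibble::tibble(
      contig_id = sample(votu_ids, n_decoy), gene_id = paste0("decoy_", seq_len(n_decoy)),
      category = sample(avg_pool, n_decoy, replace = TRUE),
      bit_score = round(runif(n_decoy, 60, 300), 1),
      aux_score = sample(4:10, n_decoy, replace = TRUE),
      amg_flags = sample(c("V", "MV"), n_decoy, replace = TRUE)
    )
    decoys$votu_id <- decoys$contig_id
    all_genes <- dplyr::bind_rows(genes, decoys)
    kept <- filter_avgs(all_genes)

    avg_sets <- split(kept$category, kept$votu_id)
    annotations <- tibble::tibble(
      votu_id = votu_ids,
      ecosystem = origin,
      quality_tier = tiers,
      host_genus = host,
      strategy = strategy,
      avg_categories = purrr::map(votu_ids, ~ unique(avg_sets[[.x]]) %||% character(0))
    )
    list(
      annotations = annotations,
      avg_genes = all_genes,
      evidence = evidence,
      truth = list(
        planted_temperate_fraction = config$temperate_fraction,
        planted_enriched_categories = list(
          lagoon = c("Vibrio", lagoon_avg), open_sea = "Pelagibacter"),
        planted_temperate = tibble::tibble(votu_id = votu_ids,
                                           temperate = planted_temperate)
      )
    )
  })
}
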