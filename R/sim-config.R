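#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the synthetic two-ecosystem and time-series
#' generators, with defaults chosen to emulate the contrasts a eutrophic
#' coastal lagoon shows against oligotrophic open-sea waters: more vOTUs
#' (richness ratio ~1.75), higher mean abundance (fold 4.8), near-disjoint
#' communities (~1% shared), a 14-point time series punctuated by two
#' episodic disturbances, and an occupancy mixture dominated by sporadic and
#' intermittent viruses with a small persistent core.
#'
#' @param seed Integer seed; every stochastic draw of a generator call flows
#'   from it and the global random state is left untouched.
#' @param n_votus_lagoon,n_votus_sea Number of vOTUs native to each ecosystem.
#' @param shared_fraction Proportion of sea vOTUs that also occur in the
#'   lagoon.
#' @param abundance_fold Ratio of lagoon to sea mean nonzero abundance
#'   (applied on the log scale of the lognormal abundance model).
#' @param n_samples_per_group Samples per ecosystem in the two-ecosystem
#'   design.
#' @param n_timepoints Length of the time series (default 14).
#' @param disturbance_timepoints Integer time indices at which an extra
#'   cohort of sporadic vOTUs is injected.
#' @param occupancy_mixture Length-3 proportions (sporadic, intermittent,
#'   persistent) summing to 1.
#' @param env_signal_r2 Planted coefficient of determination between the
#'   constructed environmental driver and the first community axis.
#' @param lognormal_mu,lognormal_sigma Log-scale mean and sd of nonzero
#'   abundances (per-gigabase scale).
#' @param detection_prob Per vOTU x sample detection probability in the
#'   two-ecosystem design.
#' @param temperate_fraction Planted fraction of temperate vOTUs per
#'   ecosystem (named or unnamed length-2, lagoon then open_sea).
#' @param enrichment_points Planted enrichment, in percentage points, of one
#'   annotation category in the lagoon group.
#'
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_votus_lagoon = 50, n_votus_sea = 30)
#' @export
sim_config <- function(seed = 1L,
                       n_votus_lagoon = 400L,
                       n_votus_sea = 230L,
                       shared_fraction = 0.01,
                       abundance_fold = 4.8,
                       n_samples_per_group = 7L,
                       n_timepoints = 14L,
                       disturbance_timepoints = c(1L, 8L),
                       occupancy_mixture = c(sporadic = 0.65,
                                             intermittent = 0.30,
                                             persistent = 0.05),
                       env_signal_r2 = 0.5,
                       lognormal_mu = 0,
                       lognormal_sigma = 1.5,
                       detection_prob = 0.6,
                       temperate_fraction = c(lagoon = 0.1, open_sea = 0.1),
                       enrichment_points = 5) {
  cfg <- list(
    seed = check_count(seed, "seed", min = 0L),
    n_votus_lagoon = check_count(n_votus_lagoon, "n_votus_lagoon"),
    n_votus_sea = check_count(n_votus_sea, "n_votus_sea"),
    shared_fraction = check_proportion(shared_fraction, "shared_fraction"),
    abundance_fold = abundance_fold,
    n_samples_per_group = check_count(n_samples_per_group, "n_samples_per_group"),
    n_timepoints = check_count(n_timepoints, "n_timepoints"),
    disturbance_timepoints = as.integer(disturbance_timepoints),
    occupancy_mixture = occupancy_mixture,
    env_signal_r2 = check_proportion(env_signal_r2, "env_signal_r2"),
    lognormal_mu = as.numeric(lognormal_mu),
    lognormal_sigma = as.numeric(lognormal_sigma),
    detection_prob = check_proportion(detection_prob, "detection_prob"),
    temperate_fraction = temperate_fraction,
    enrichment_points = as.numeric(enrichment_points)
  )
  if (!is.numeric(abundance_fold) || length(abundance_fold) != 1L ||
      is.na(abundance_fold) || abundance_fold <= 0) {
    abort("`abundance_fold` must be a single positive ratio.")
  }
  if (length(cfg$occupancy_mixture) != 3L || anyNA(cfg$occupancy_mixture) ||
      any(cfg$occupancy_mixture < 0) || any(cfg$occupancy_mixture > 1)) {
    abort("`occupancy_mixture` must be three proportions in [0, 1].")
  }
  if (abs(sum(cfg$occupancy_mixture) - 1) > 1e-9) {
    abort("`occupancy_mixture` must sum to 1 (within 1e-9).")
  }
  names(cfg$occupancy_mixture) <- c("sporadic", "intermittent", "persistent")
  if (any(cfg$disturbance_timepoints < 1L) ||
      any(cfg$disturbance_timepoints > cfg$n_timepoints)) {
    abort("`disturbance_timepoints` must lie within 1..n_timepoints.")
  }
  if (length(cfg$temperate_fraction) != 2L ||
      any(cfg$temperate_fraction < 0) || any(cfg$temperate_fraction > 1)) {
    abort("`temperate_fraction` must be two proportions in [0, 1].")
  }
  names(cfg$temperate_fraction) <- c("lagoon", "open_sea")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}
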