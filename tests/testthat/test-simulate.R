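test_that("config validation names the offending field", {
  expect_error(sim_config(n_votus_lagoon = 1), "n_votus_lagoon")
  expect_error(sim_config(shared_fraction = 1.2), "shared_fraction")
  expect_error(sim_config(occupancy_mixture = c(0.5, 0.5, 0.5)),
               "occupancy_mixture")
  expect_error(sim_config(disturbance_timepoints = 99),
               "disturbance_timepoints")
  expect_error(sim_config(abundance_fold = -1), "abundance_fold")
})

test_that("generators are bit-identical under a fixed seed and leave the RNG alone", {
  cfg <- sim_config(seed = 7, n_votus_lagoon = 40, n_votus_sea = 25,
                    n_samples_per_group = 4)
  set.seed(123)
  before <- .Random.seed
  a <- simulate_two_ecosystems(cfg)
  expect_identical(before, .Random.seed)
  b <- simulate_two_ecosystems(cfg)
  expect_identical(a$abundance, b$abundance)
  expect_identical(a$metadata, b$metadata)

  t1 <- simulate_time_series(cfg)
  t2 <- simulate_time_series(cfg)
  expect_identical(t1$abundance, t2$abundance)

  an1 <- simulate_annotations(rownames(a$abundance), cfg)
  an2 <- simulate_annotations(rownames(a$abundance), cfg)
  expect_identical(an1$annotations, an2$annotations)
})

test_that("disjoint communities arise when no vOTUs are shared", {
  sim <- simulate_two_ecosystems(sim_config(seed = 2, shared_fraction = 0,
                                            n_votus_lagoon = 60,
                                            n_votus_sea = 40))
  eco <- sim$metadata$ecosystem
  in_lagoon <- rownames(sim$abundance)[
    rowSums(sim$abundance[, eco == "lagoon"]) > 0]
  in_sea <- rownames(sim$abundance)[
    rowSums(sim$abundance[, eco == "open_sea"]) > 0]
  expect_equal(sorensen_dice(in_lagoon, in_sea)$dice_percent, 0)
})

test_that("equal generating conditions give non-significant abundance contrasts", {
  # fold 1 and equal richness: the rank-sum test on per-sample mean
  # abundance should reject at ~nominal rate only
  rejected <- vapply(1:100, function(s) {
    sim <- simulate_two_ecosystems(
      sim_config(seed = s, abundance_fold = 1, n_votus_lagoon = 60,
                 n_votus_sea = 60, n_samples_per_group = 5))
    eco <- sim$metadata$ecosystem
    means <- colMeans(sim$abundance)
    wilcoxon_rank_sum(means[eco == "lagoon"], means[eco == "open_sea"])$p < 0.05
  }, logical(1))
  expect_gte(mean(!rejected), 0.90)
})

test_that("increasing abundance_fold increases the recovered lagoon/sea ratio", {
  recovered <- function(fold) {
    mean(vapply(1:10, function(s) {
      sim <- simulate_two_ecosystems(
        sim_config(seed = s, abundance_fold = fold, n_votus_lagoon = 80,
                   n_votus_sea = 80, n_samples_per_group = 5))
      eco <- sim$metadata$ecosystem
      x <- sim$abundance
      lag <- x[, eco == "lagoon"]
      sea <- x[, eco == "open_sea"]
      mean(lag[lag > 0]) / mean(sea[sea > 0])
    }, numeric(1)))
  }
  r <- vapply(c(1, 2, 4, 8), recovered, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("a pure persistent mixture yields only high-occupancy vOTUs", {
  sim <- simulate_time_series(
    sim_config(seed = 4, n_votus_lagoon = 50,
               occupancy_mixture = c(0, 0, 1),
               disturbance_timepoints = integer(0)))
  det <- rowSums(sim$abundance > 0)
  expect_true(all(det / ncol(sim$abundance) > 0.75))
})

test_that("planted occupancy classes are recovered exactly", {
  sim <- simulate_time_series(sim_config(seed = 5, n_votus_lagoon = 120))
  cls <- classify_dynamics(sim$abundance)
  truth <- sim$truth$votu_classes
  merged <- dplyr::inner_join(cls, truth, by = "votu_id")
  expect_equal(nrow(merged), nrow(truth))  # every vOTU detected somewhere
  expect_identical(merged$class, merged$planted_class)
})

test_that("disturbances inflate the sporadic fraction at their timepoint", {
  sim <- simulate_time_series(sim_config(seed = 6, n_votus_lagoon = 150,
                                         disturbance_timepoints = 5L))
  fr <- dynamics_fractions(sim$abundance)
  spor <- fr[fr$class == "sporadic", ]
  at5 <- spor$percent[spor$timepoint == "T05"]
  expect_gt(at5, median(spor$percent))
})

test_that("a zeroed environmental signal leaves the planted variable exchangeable", {
  # with env_signal_r2 = 0 the planted column is built from pure noise, so
  # its envfit p-value should be approximately uniform across seeds
  pvals <- vapply(1:60, function(s) {
    sim <- simulate_time_series(
      sim_config(seed = s, n_votus_lagoon = 60, env_signal_r2 = 0))
    ord <- pcoa_ordination(aitchison_distance(clr_transform(sim$abundance)))
    ef <- envfit_vectors(ord, sim$metadata[c("sample_id", "iz_percent")],
                         n_perm = 99, seed = s)
    ef$p
  }, numeric(1))
  expect_gt(mean(pvals > 0.05), 0.80)
  # permutation p-values live on the grid k/100: under exchangeability the
  # fraction at or below 0.25 is binomial around 0.25
  ci <- qbinom(c(0.025, 0.975), 60, 0.25) / 60
  expect_gte(mean(pvals <= 0.25), ci[1])
  expect_lte(mean(pvals <= 0.25), ci[2])
})

test_that("coverage profiles honour planted breadth and depth", {
  cov <- simulate_coverage(lengths = 1000, breadth = 0.5, mean_depth = 4,
                           seed = 1)
  expect_gte(cov$breadth, 0.45)
  expect_lte(cov$breadth, 0.55)
  expect_equal(cov$breadth, mean(cov$depth[[1]] > 0))

  const <- simulate_coverage(lengths = 500, breadth = 1, mean_depth = 4,
                             seed = 2, depth_model = "constant")
  expect_equal(const$trimmed_mean_depth, 4)

  none <- simulate_coverage(lengths = 500, breadth = 0, mean_depth = 4, seed = 3)
  expect_equal(none$breadth, 0)
  expect_equal(none$trimmed_mean_depth, 0)
  expect_error(simulate_coverage(lengths = 0), "lengths")
})

test_that("planted temperate fraction zero yields no temperate vOTUs", {
  ann <- simulate_annotations(
    sprintf("v%03d", 1:200),
    sim_config(seed = 8, temperate_fraction = c(0, 0)))
  expect_false(any(ann$annotations$strategy == "temperate"))
})

test_that("planted category enrichment is recovered in sign", {
  # +5-point lagoon enrichment of two AVG categories; the median-difference
  # effect size should be positive for the planted categories
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = s, n_votus_lagoon = 300, n_votus_sea = 300,
                      shared_fraction = 0, n_samples_per_group = 7)
    sim <- simulate_two_ecosystems(cfg)
    origin <- ifelse(sim$truth$votu_origin$origin == "open_sea",
                     "open_sea", "lagoon")
    ann <- simulate_annotations(rownames(sim$abundance), cfg, origin = origin)
    grp <- setNames(sim$metadata$ecosystem, sim$metadata$sample_id)
    ec <- effect_size_contrast(sim$abundance, ann$annotations, grp, "avg",
                               exclude_shared = TRUE)
    planted <- ann$truth$planted_enriched_categories$lagoon
    planted <- setdiff(planted, "Vibrio")
    all(ec$effect_size[ec$category %in% planted] > 0)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
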