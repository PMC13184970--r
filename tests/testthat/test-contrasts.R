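test_that("Sorensen-Dice overlap equals the classic two-set formula", {
  expect_equal(sorensen_dice(letters[1:3], letters[1:3])$dice_percent, 100)
  expect_equal(sorensen_dice(letters[1:3], letters[4:6])$dice_percent, 0)
  r <- sorensen_dice(c("a", "b", "c"), c("a", "b", "d", "e", "f"))
  expect_equal(r$dice_percent, 50)  # 100 * 2 / mean(3, 5)
  expect_equal(r$n_shared, 2L)
  expect_error(sorensen_dice(character(0), "a"), "non-empty")

  withr::with_seed(1, {
    for (i in 1:20) {
      a <- sample(letters, sample(3:15, 1))
      b <- sample(letters, sample(3:15, 1))
      ab <- sorensen_dice(a, b)$dice_percent
      ba <- sorensen_dice(b, a)$dice_percent
      classic <- 100 * 2 * length(intersect(a, b)) / (length(a) + length(b))
      expect_equal(ab, ba)
      expect_equal(ab, classic)
    }
  })
})

test_that("temperate calls honour the inclusive evidence thresholds", {
  ev <- tibble::tibble(
    quality_tier = c("low", "low", "high", "high", "complete", "medium"),
    recombinase_bitscore = c(50.0, 49.9, NA, NA, NA, NA),
    lifestyle = c(NA, NA, "temperate", "virulent", "virulent", "temperate"),
    lifestyle_probability = c(NA, NA, 0.96, 0.95, 0.949, 0.99))
  expect_identical(
    call_temperate(ev),
    c("temperate",      # bit score exactly 50
      "undetermined",   # 49.9 falls short, no lifestyle call
      "temperate",      # probability 0.96 on high-quality genome
      "virulent",       # probability exactly 0.95
      "undetermined",   # probability below 0.95
      "undetermined"))  # medium quality: lifestyle call not trusted
})

test_that("AVG filtering keeps auxiliary score <= 3, bit >= 60, no V flag", {
  genes <- tibble::tibble(
    contig_id = paste0("c", 1:5),
    category = "x",
    bit_score = c(80, 59.9, 60, 200, 70),
    aux_score = c(3, 2, 1, 4, 2),
    amg_flags = c("", "", "M", "", "V"))
  kept <- filter_avgs(genes)
  expect_identical(kept$contig_id, c("c1", "c3"))
})

test_that("contig labels propagate to vOTUs with union/any semantics", {
  cl <- cluster_votus(
    c(A = 9000, B = 8000, C = 7000, D = 6000),
    tibble::tibble(contig_a = c("A", "A"), contig_b = c("B", "C"),
                   ani_percent = c(99, 98),
                   aligned_fraction_shorter = c(0.95, 0.9)))
  ev <- tibble::tibble(
    contig_id = c("A", "B", "C", "D"),
    quality_tier = c("high", "low", "low", "low"),
    host_genus = c("Vibrio", NA, NA, NA),
    recombinase_bitscore = c(NA, 72, NA, NA),
    lifestyle = NA_character_, lifestyle_probability = NA_real_)
  genes <- tibble::tibble(
    contig_id = c("A", "B"), category = c("X", "Y"),
    bit_score = 100, aux_score = 1, amg_flags = "")
  ann <- propagate_contig_labels(ev, cl, genes)
  abc <- ann[ann$representative_id == "A", ]
  expect_equal(abc$n_contigs, 3L)
  expect_equal(abc$strategy, "temperate")  # one temperate member suffices
  expect_equal(abc$host_genus, "Vibrio")   # representative's host
  expect_setequal(abc$avg_categories[[1]], c("X", "Y"))  # union over members
  d <- ann[ann$representative_id == "D", ]
  expect_equal(d$strategy, "undetermined")
  expect_length(d$avg_categories[[1]], 0)

  expect_error(
    propagate_contig_labels(
      tibble::tibble(contig_id = "Z", quality_tier = "low"), cl),
    "missing from clustering")
})

test_that("label propagation is idempotent", {
  cl <- cluster_votus(c(A = 9000, B = 8000),
                      tibble::tibble(contig_a = "A", contig_b = "B",
                                     ani_percent = 99,
                                     aligned_fraction_shorter = 0.9))
  ev <- tibble::tibble(contig_id = c("A", "B"),
                       quality_tier = c("high", "low"),
                       recombinase_bitscore = c(NA, 88))
  once <- propagate_contig_labels(ev, cl)
  # re-propagating the vOTU-level labels through a singleton clustering
  cl2 <- cluster_votus(c(A = 9000),
                       tibble::tibble(contig_a = character(),
                                      contig_b = character(),
                                      ani_percent = double(),
                                      aligned_fraction_shorter = double()))
  ev2 <- tibble::tibble(contig_id = "A", quality_tier = once$quality_tier,
                        recombinase_bitscore = 88)
  twice <- propagate_contig_labels(ev2, cl2)
  expect_equal(twice$strategy, once$strategy)
})

test_that("AVG carrier percentage is exact to one decimal and order-invariant", {
  expect_equal(avg_carrier_percent(1754, 30637), 5.7)
  expect_equal(avg_carrier_percent(0, 100), 0)
  expect_equal(avg_carrier_percent(100, 100), 100)
  expect_error(avg_carrier_percent(5, 0), "n_total")

  ann <- tibble::tibble(
    votu_id = paste0("v", 1:10),
    avg_categories = c(rep(list("x"), 3), rep(list(character(0)), 7)))
  expect_equal(avg_carrier_percent(ann), 30)
  expect_equal(avg_carrier_percent(ann[sample(10), ]), 30)
})

test_that("per-sample category percentages include explicit zeros", {
  m <- toy_matrix(matrix(c(1, 1, 1, 1,
                           1, 0, 0, 0), 4, 2), samples = c("s1", "s2"))
  ann <- tibble::tibble(
    votu_id = rownames(m),
    host_genus = NA_character_,
    strategy = c("temperate", "temperate", "temperate", "virulent"),
    avg_categories = rep(list(character(0)), 4))
  pct <- per_sample_category_percent(m, ann, "strategy")
  s1 <- pct[pct$sample_id == "s1", ]
  expect_equal(s1$percent[s1$category == "temperate"], 75)
  expect_equal(s1$percent[s1$category == "virulent"], 25)
  # s2 detects only temperate vOTUs: virulent appears as an explicit zero
  s2 <- pct[pct$sample_id == "s2", ]
  expect_equal(s2$percent[s2$category == "temperate"], 100)
  expect_equal(s2$percent[s2$category == "virulent"], 0)

  # sample without assigned detections is omitted with a warning
  m2 <- cbind(m, s3 = c(0, 0, 0, 0))
  expect_warning(per_sample_category_percent(m2, ann, "strategy"),
                 "omitted")
})

test_that("effect-size contrasts apply the >=5-vOTU and >=0.1-point filters", {
  withr::with_seed(2, {
    n <- 24
    m <- toy_matrix(matrix(rlnorm(n * 8), n, 8),
                    samples = sprintf("s%02d", 1:8))
    grp <- setNames(rep(c("lagoon", "open_sea"), each = 4), colnames(m))
    ann <- tibble::tibble(
      votu_id = rownames(m),
      host_genus = NA_character_,
      strategy = NA_character_,
      avg_categories = c(rep(list("rare"), 4),        # 4 vOTUs: fails >=5
                         rep(list("common"), 12),
                         rep(list(character(0)), 8)))
    res <- effect_size_contrast(m, ann, grp, "avg")
    rare <- res[res$category == "rare", ]
    expect_false(rare$included)
    expect_match(rare$exclusion_reason, "fewer than 5")
    expect_true(is.na(rare$p_adjusted))
  })

  # identical percent distributions: zero effect, excluded by the 0.1 rule
  m <- toy_matrix(matrix(1, 6, 6), samples = paste0("s", 1:6))
  grp <- setNames(rep(c("a", "b"), each = 3), colnames(m))
  ann <- tibble::tibble(
    votu_id = rownames(m), host_genus = NA_character_,
    strategy = NA_character_,
    avg_categories = rep(list("cat"), 6))
  res <- effect_size_contrast(m, ann, grp, "avg")
  expect_equal(res$effect_size, 0)
  expect_false(res$included)
  expect_match(res$exclusion_reason, "median difference")
})

test_that("excluding shared vOTUs is a no-op for disjoint groups", {
  sim <- simulate_two_ecosystems(
    sim_config(seed = 3, shared_fraction = 0, n_votus_lagoon = 80,
               n_votus_sea = 80, n_samples_per_group = 4))
  ann <- simulate_annotations(
    rownames(sim$abundance), sim_config(seed = 3),
    origin = ifelse(sim$truth$votu_origin$origin == "open_sea",
                    "open_sea", "lagoon"))
  grp <- setNames(sim$metadata$ecosystem, sim$metadata$sample_id)
  with_excl <- effect_size_contrast(sim$abundance, ann$annotations, grp,
                                    "avg", exclude_shared = TRUE)
  without <- effect_size_contrast(sim$abundance, ann$annotations, grp,
                                  "avg", exclude_shared = FALSE)
  expect_equal(with_excl, without)
})

test_that("Spearman correlation matches the exact rank formula", {
  r <- spearman_env_correlation(c(1, 2, 3, 4), c(1, 2, 4, 3))
  expect_equal(r$statistic, 0.8)  # 1 - 6*2 / (4*15)
  expect_equal(spearman_env_correlation(1:5, 1:5)$statistic, 1)
  expect_equal(spearman_env_correlation(1:5, 5:1)$statistic, -1)
  expect_warning(rc <- spearman_env_correlation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(rc$statistic))
})

test_that("heatmap matrices are log10(x+1) with reproducible leaf order", {
  m <- toy_matrix(matrix(c(0, 9, 99, 0, 9, 99), 3, 2))
  hm <- heatmap_matrix(m)
  expect_equal(sort(unique(as.numeric(hm$values))), c(0, 1, 2))
  # identical rows merge at height zero and sit adjacently
  m2 <- rbind(a = c(1, 2, 3), b = c(50, 0, 4), a2 = c(1, 2, 3))
  colnames(m2) <- paste0("s", 1:3)
  hm2 <- heatmap_matrix(m2)
  pos <- match(c("a", "a2"), hm2$row_order)
  expect_equal(abs(diff(pos)), 1)
  expect_equal(min(hm2$hclust$height), 0)
})
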