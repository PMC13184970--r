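# Annotation-based contrasts between groups of viral communities: set
# overlap, label propagation from contigs to vOTUs, the temperate/virulent
# call, auxiliary-gene filtering, per-sample category percentages and the
# filtered effect-size procedure.

#' Sorensen-Dice overlap of two vOTU sets
#'
#' `100 * |A intersect B| / mean(|A|, |B|)` — algebraically identical to the
#' classic `2|A^B|/(|A|+|B|) * 100`.
#'
#' @param set_a,set_b Non-empty character vectors of vOTU ids.
#' @param group_a,group_b Optional labels for the output row.
#' @return A one-row tibble: group_a, group_b, n_a, n_b, n_shared,
#'   dice_percent.
#' @examples
#' sorensen_dice(c("a", "b", "c"), c("a", "b", "d", "e", "f"))  # 50
#' @export
sorensen_dice <- function(set_a, set_b, group_a = "A", group_b = "B") {
  if (length(set_a) == 0 || length(set_b) == 0) {
    abort("both sets must be non-empty.")
  }
  a <- unique(set_a)
  b <- unique(set_b)
  shared <- length(intersect(a, b))
  tibble::tibble(
    group_a = group_a, group_b = group_b,
    n_a = length(a), n_b = length(b), n_shared = shared,
    dice_percent = 100 * shared / ((length(a) + length(b)) / 2)
  )
}

#' Call the replicative strategy of a contig from its evidence
#'
#' A contig is called temperate if a lifestyle classifier assigned
#' "temperate" with probability >= 0.95 on a complete or high-quality
#' genome, or if any recombinase HMM hit reached bit score >= 50 (both
#' bounds inclusive); virulent if the classifier assigned "virulent" with
#' probability >= 0.95 on a complete/high-quality genome; otherwise
#' undetermined.
#'
#' @param evidence Tibble with columns `quality_tier`,
#'   `recombinase_bitscore`, `lifestyle`, `lifestyle_probability` (NAs
#'   allowed).
#' @return Character vector (`"temperate"`, `"virulent"`,
#'   `"undetermined"`), one per row.
#' @export
call_temperate <- function(evidence) {
  hq <- evidence$quality_tier %in% c("complete", "high")
  prob <- evidence$lifestyle_probability
  life <- evidence$lifestyle
  bits <- evidence$recombinase_bitscore
  lifestyle_ok <- hq & !is.na(prob) & prob >= 0.95
  temperate <- (lifestyle_ok & !is.na(life) & life == "temperate") |
    (!is.na(bits) & bits >= 50)
  virulent <- lifestyle_ok & !is.na(life) & life == "virulent" & !temperate
  dplyr::case_when(temperate ~ "temperate",
                   virulent ~ "virulent",
                   TRUE ~ "undetermined")
}

#' Filter auxiliary viral gene annotations
#'
#' Retains gene rows with annotation bit score >= 60, auxiliary score <= 3
#' and no "V" among the flags (a V flag marks a gene on a viral-hallmark
#' context, excluded from the auxiliary set).
#'
#' @param genes Tibble with `bit_score`, `aux_score`, `amg_flags`.
#' @return The retained rows.
#' @export
filter_avgs <- function(genes) {
  need <- c("bit_score", "aux_score", "amg_flags")
  if (!all(need %in% names(genes))) {
    abort("`genes` needs columns bit_score, aux_score, amg_flags.")
  }
  flags <- ifelse(is.na(genes$amg_flags), "", genes$amg_flags)
  genes[genes$bit_score >= 60 & genes$aux_score <= 3 &
          !grepl("V", flags, fixed = TRUE), , drop = FALSE]
}

#' Propagate contig-level annotations to vOTUs
#'
#' A vOTU is temperate if any member contig is called temperate (members of
#' a cluster putatively belong to the same viral population); its
#' auxiliary-gene category set is the union over members; host genus and
#' genome quality are taken from the representative contig. Applying the
#' propagation twice equals applying it once.
#'
#' @param evidence Per-contig tibble with `contig_id`, `quality_tier`,
#'   `host_genus` (optional), `recombinase_bitscore`, `lifestyle`,
#'   `lifestyle_probability`.
#' @param clustering A [cluster_votus()] result covering every annotated
#'   contig.
#' @param avg_genes Optional retained gene rows ([filter_avgs()]) with
#'   `contig_id` and `category`.
#' @return A vOTU-level tibble: votu_id, representative_id, n_contigs,
#'   quality_tier, host_genus, strategy, avg_categories (list-column).
#' @export
propagate_contig_labels <- function(evidence, clustering, avg_genes = NULL) {
  members <- clustering$members
  for (col in c("quality_tier", "host_genus", "lifestyle")) {
    if (!col %in% names(evidence)) evidence[[col]] <- NA_character_
  }
  for (col in c("lifestyle_probability", "recombinase_bitscore")) {
    if (!col %in% names(evidence)) evidence[[col]] <- NA_real_
  }
  unknown <- setdiff(evidence$contig_id, members$contig_id)
  if (length(unknown) > 0) {
    abort(sprintf("annotated contig(s) missing from clustering: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  ev <- dplyr::left_join(members, evidence, by = "contig_id")
  ev$contig_strategy <- call_temperate(ev)
  avg_by_contig <- if (is.null(avg_genes) || nrow(avg_genes) == 0) list() else
    split(avg_genes$category, avg_genes$contig_id)
  ev |>
    dplyr::group_by(.data$votu_id, .data$representative_id) |>
    dplyr::summarise(
      n_contigs = dplyr::n(),
      quality_tier = .data$quality_tier[.data$is_representative][1] %||% NA_character_,
      host_genus = .data$host_genus[.data$is_representative][1] %||% NA_character_,
      strategy = if (any(.data$contig_strategy == "temperate")) "temperate"
        else if (any(.data$contig_strategy == "virulent")) "virulent"
        else "undetermined",
      avg_categories = list(sort(unique(unlist(
        avg_by_contig[.data$contig_id], use.names = FALSE)))),
      .groups = "drop"
    )
}

#' Percentage of vOTUs carrying at least one auxiliary viral gene
#'
#' `100 * carriers / total`, reported to one decimal.
#'
#' @param annotations vOTU-level tibble with list-column `avg_categories`,
#'   or a single carrier count.
#' @param n_total Total number of vOTUs (defaults to `nrow(annotations)`).
#' @return Percentage to one decimal.
#' @examples
#' avg_carrier_percent(1754, 30637)  # 5.7
#' @export
avg_carrier_percent <- function(annotations, n_total = NULL) {
  if (is.numeric(annotations) && length(annotations) == 1) {
    carriers <- annotations
    if (is.null(n_total)) abort("`n_total` is required with a carrier count.")
  } else {
    carriers <- sum(lengths(annotations$avg_categories) > 0)
    if (is.null(n_total)) n_total <- nrow(annotations)
  }
  if (n_total <= 0) abort("`n_total` must be > 0.")
  round(100 * carriers / n_total, 1)
}

#' Per-sample percentages of annotation categories among detected vOTUs
#'
#' For each sample, among the vOTUs detected there (abundance > 0), the
#' percentage belonging to each category of the chosen annotation type.
#' With `denominator = "assigned"` (default) the denominator is the count
#' of detected vOTUs with any assignment of that type, so the unannotated
#' pool does not dilute the percentages; `"all"` uses every detected vOTU.
#' Categories observed in the table but absent from a sample contribute
#' explicit zero rows, so downstream effect sizes include zeros.
#'
#' @param x vOTU x sample abundance matrix.
#' @param annotations vOTU-level annotation tibble
#'   ([propagate_contig_labels()] / [simulate_annotations()]).
#' @param category_type `"host"`, `"strategy"` or `"avg"`.
#' @param denominator `"assigned"` (default) or `"all"`.
#' @return A tibble: sample_id, category, n_votus, percent.
#' @export
per_sample_category_percent <- function(x, annotations,
                                        category_type = c("host", "strategy", "avg"),
                                        denominator = c("assigned", "all")) {
  category_type <- match.arg(category_type)
  denominator <- match.arg(denominator)
  check_abundance_matrix(x)
  assign_tbl <- category_assignments(annotations, category_type)
  categories <- sort(unique(assign_tbl$category))
  if (length(categories) == 0) abort("no category assignments of this type.")
  out <- purrr::map_dfr(colnames(x), function(s) {
    detected <- rownames(x)[x[, s] > 0]
    hits <- assign_tbl[assign_tbl$votu_id %in% detected, , drop = FALSE]
    denom <- if (denominator == "assigned") length(unique(hits$votu_id)) else
      length(detected)
    if (denom == 0) return(NULL)
    counts <- table(factor(hits$category, levels = categories))
    tibble::tibble(sample_id = s, category = categories,
                   n_votus = as.integer(counts),
                   percent = 100 * as.numeric(counts) / denom)
  })
  n_empty <- length(setdiff(colnames(x), out$sample_id))
  if (n_empty > 0) {
    warn(sprintf("%d sample(s) without assigned detected vOTUs omitted.", n_empty))
  }
  out
}

# long (votu_id, category) assignments for one annotation type
category_assignments <- function(annotations, category_type) {
  switch(category_type,
    host = {
      keep <- !is.na(annotations$host_genus)
      tibble::tibble(votu_id = annotations$votu_id[keep],
                     category = annotations$host_genus[keep])
    },
    strategy = {
      keep <- annotations$strategy %in% c("temperate", "virulent")
      tibble::tibble(votu_id = annotations$votu_id[keep],
                     category = annotations$strategy[keep])
    },
    avg = {
      tidy <- tibble::tibble(votu_id = annotations$votu_id,
                             category = annotations$avg_categories)
      tidyr::unnest(tidy, "category")
    }
  )
}

#' Filtered effect-size contrasts of annotation categories between groups
#'
#' For two groups of samples, computes per-sample category percentages
#' (zeros included), tests each category with a two-sided Wilcoxon rank-sum
#' across samples, and reports the effect size as the difference of group
#' medians (group A minus group B). Categories are flagged `included` only
#' if at least one group holds >= 5 vOTUs of the category and the absolute
#' median difference is >= 0.1 percentage points; FDR adjustment is applied
#' over the included categories. When `exclude_shared = TRUE` (appropriate
#' for strategy and AVG contrasts, whose annotations derive from contigs in
#' clusters), vOTUs detected in both groups are removed first.
#'
#' @param x vOTU x sample abundance matrix covering both groups.
#' @param annotations vOTU-level annotation tibble.
#' @param groups Named group label per sample (names = sample ids), two
#'   levels.
#' @param category_type `"host"`, `"strategy"` or `"avg"`.
#' @param exclude_shared Drop vOTUs detected in both groups first.
#' @param denominator Passed to [per_sample_category_percent()].
#' @param min_votus,min_effect Inclusion filters (defaults 5 and 0.1).
#' @return A tibble, one row per category: medians, effect_size, p,
#'   p_adjusted (NA when excluded), vOTU counts per group, included flag
#'   and exclusion reason.
#' @export
effect_size_contrast <- function(x, annotations, groups,
                                 category_type = c("host", "strategy", "avg"),
                                 exclude_shared = FALSE,
                                 denominator = c("assigned", "all"),
                                 min_votus = 5L, min_effect = 0.1) {
  category_type <- match.arg(category_type)
  denominator <- match.arg(denominator)
  check_abundance_matrix(x)
  if (is.null(names(groups))) abort("`groups` must be named by sample id.")
  groups <- groups[colnames(x)]
  lv <- sort(unique(groups))
  if (length(lv) != 2) abort("exactly two groups are required.")
  if (min(table(groups)) < 2) abort("each group needs >= 2 samples.")

  if (exclude_shared) {
    det_a <- rowSums(x[, groups == lv[1], drop = FALSE] > 0) > 0
    det_b <- rowSums(x[, groups == lv[2], drop = FALSE] > 0) > 0
    x <- x[!(det_a & det_b), , drop = FALSE]
  }
  pct <- suppressWarnings(
    per_sample_category_percent(x, annotations, category_type, denominator))
  pct$group <- groups[pct$sample_id]

  # group-level vOTU counts per category (distinct vOTUs detected in group)
  count_votus <- function(g) {
    detected <- rownames(x)[rowSums(x[, groups == g, drop = FALSE] > 0) > 0]
    hits <- category_assignments(annotations, category_type)
    hits <- hits[hits$votu_id %in% detected, , drop = FALSE]
    table(hits$category)
  }
  cnt_a <- count_votus(lv[1])
  cnt_b <- count_votus(lv[2])

  res <- pct |>
    dplyr::group_by(.data$category) |>
    dplyr::group_modify(function(df, key) {
      pa <- df$percent[df$group == lv[1]]
      pb <- df$percent[df$group == lv[2]]
      wt <- if (length(pa) >= 2 && length(pb) >= 2) wilcoxon_rank_sum(pa, pb)
        else test_result("wilcoxon_rank_sum", NA_real_, NA_real_)
      tibble::tibble(
        group_a = lv[1], group_b = lv[2],
        median_a = median(pa), median_b = median(pb),
        effect_size = median(pa) - median(pb),
        n_votus_a = as.integer(cnt_a[key$category] %||% 0L),
        n_votus_b = as.integer(cnt_b[key$category] %||% 0L),
        statistic = wt$statistic, p = wt$p
      )
    }) |>
    dplyr::ungroup()
  res$n_votus_a[is.na(res$n_votus_a)] <- 0L
  res$n_votus_b[is.na(res$n_votus_b)] <- 0L
  res$included <- pmax(res$n_votus_a, res$n_votus_b) >= min_votus &
    abs(res$effect_size) >= min_effect & !is.na(res$p) & !is.nan(res$p)
  res$exclusion_reason <- dplyr::case_when(
    res$included ~ NA_character_,
    pmax(res$n_votus_a, res$n_votus_b) < min_votus ~
      sprintf("fewer than %d vOTUs in both groups", min_votus),
    abs(res$effect_size) < min_effect ~
      sprintf("absolute median difference below %g", min_effect),
    TRUE ~ "test not computable"
  )
  res$p_adjusted <- NA_real_
  if (any(res$included)) {
    res$p_adjusted[res$included] <- adjust_fdr(res$p[res$included])
  }
  res
}

#' Spearman correlation between two time series
#'
#' Mid-rank Spearman rho with a two-sided p-value (exact for n < 10
#' without ties, t-approximation otherwise). Constant series are flagged
#' and return NA.
#'
#' @param a,b Paired numeric series, n >= 4.
#' @return A one-row result tibble; `statistic` is rho.
#' @examples
#' spearman_env_correlation(1:4, c(1, 2, 4, 3))  # rho = 0.8
#' @export
spearman_env_correlation <- function(a, b) {
  if (length(a) != length(b) || length(a) < 4) {
    abort("need >= 4 paired observations.")
  }
  if (length(unique(a)) < 2 || length(unique(b)) < 2) {
    warn("constant series; correlation undefined.")
    return(test_result("spearman", NA_real_, NA_real_, note = "constant series"))
  }
  ct <- suppressWarnings(cor.test(a, b, method = "spearman"))
  test_result("spearman", statistic = unname(ct$estimate), p = ct$p.value)
}

#' Log-transformed, row-clustered matrix for heatmap display
#'
#' Transforms to log10(x + 1) and hierarchically clusters the rows
#' (average linkage on Euclidean distance), emitting the leaf order so the
#' plot is reproducible.
#'
#' @param x Non-negative matrix (e.g. summed abundances per category over
#'   time).
#' @return A list of class `heatmap_matrix`: `values` (transformed,
#'   rows in leaf order), `row_order`, `hclust` (or `NULL` for < 3 rows).
#' @export
heatmap_matrix <- function(x) {
  if (!is.matrix(x) || any(x < 0)) abort("`x` must be a non-negative matrix.")
  v <- log10(x + 1)
  if (nrow(v) >= 3) {
    hc <- hclust(dist(v, method = "euclidean"), method = "average")
    ord <- hc$order
  } else {
    hc <- NULL
    ord <- seq_len(nrow(v))
  }
  structure(list(values = v[ord, , drop = FALSE],
                 row_order = rownames(v)[ord] %||% ord, hclust = hc),
            class = "heatmap_matrix")
}

#' @export
print.heatmap_matrix <- function(x, ...) {
  cat(sprintf("<heatmap_matrix> %d x %d, log10(x + 1), average linkage\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
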