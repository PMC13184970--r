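---
title: "Methods: community ecology of vOTUs from metagenomic time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community ecology of vOTUs from metagenomic time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

votuecol implements the statistical ecology that follows viral identification
in shotgun metagenomics: once viral contigs have been identified and
pairwise nucleotide similarities computed, the package takes over —
clustering contigs into viral operational taxonomic units (vOTUs),
normalizing read-mapping coverage into relative abundances, and running the
comparative and temporal community analyses that characterize viral
assemblages across ecosystems and through time. This vignette records the
models, the tunable parameters, the numerical conventions, and the design
choices behind each stage, together with what the synthetic-data generator
does and does not emulate.

```{r setup}
library(votuecol)
```

## From coverage to abundance

**vOTU clustering.** Contigs are clustered greedily: sorted longest first
(ties broken lexicographically by id), each contig joins the first
already-founded representative with average nucleotide identity ≥ 95% and
aligned fraction of the shorter sequence ≥ 80%, else founds a new cluster.
Both thresholds are inclusive and exposed (`ani_min`, `af_min`); the founder
— necessarily the longest member — is the representative, the standard
centroid convention. Because passing pairs are symmetrized into a set before
the greedy pass, the result cannot depend on the order of the similarity
records; the test suite additionally verifies the greedy pass against a
literal re-statement of the centroid rule on hundreds of random instances.

**Abundance.** Per contig and sample, the trimmed mean of per-position read
depth (default `trim = 0.05` per tail: the tool that popularized the
statistic does not publish its fraction, and 5% is the common
coverage-tooling default; `trimmed_mean()` removes `floor(trim * L)`
positions per tail, so `trim = 0` is exactly the arithmetic mean) is
divided by the sample's total quality-trimmed bases and multiplied by 1e9,
giving abundance per metagenome gigabase. A detection (breadth) filter
precedes normalization: a contig covered over less than 70% of its length
in a sample is treated as not detected there and its abundance set to zero
rather than dropped, which keeps the matrix shape stable across samples
(the read-identity and read-alignment requirements of mapping are assumed
applied upstream, where the coverage summaries are produced). The 70% bound
retains breadth exactly at the threshold.

## Compositional analysis

Per-gigabase abundances are zero-inflated compositions, so all
between-sample geometry runs through the centered log-ratio (CLR):
`clr_i = ln(x_i + c) − mean_j ln(x_j + c)` per sample, with pseudo-count
`c = 0.001` on the per-gigabase scale. Closure (re-normalizing each sample
to a constant sum) before or after is immaterial to the CLR on strictly
positive data, so it is omitted; with the pseudo-count present the
transform is only approximately closure-invariant, which is why the
invariance test runs on positive matrices with `pseudo_count = 0`. Every
sample's CLR values sum to zero by construction (tested to 1e-9).

Aitchison distance is the Euclidean distance between CLR vectors.
Principal coordinates use classical metric scaling (`stats::cmdscale`):
double-centering of −½d², eigendecomposition, coordinates scaled by the
square root of each positive eigenvalue; the percent variance per axis is
computed over positive eigenvalues only. Since Aitchison distances are
exactly Euclidean, no meaningful negative eigenvalues arise (tested), and
the full-coordinate embedding reproduces the input distances to 1e-8.

Shannon diversity uses the natural log: the published diversity values this
package is designed to reproduce exceed 8.2 at richness above 6000, which
is only consistent with natural-log units (ln 6000 ≈ 8.70). Evenness is
`H / ln S`, undefined (returned as `NA`) below two detected vOTUs; richness
is additionally reported per gigabase of quality-trimmed reads.

## Group structure and environmental fitting

**k-means with silhouette selection.** For each candidate k (default
2…min(8, n−1)), k-means runs with 100 restarts and the mean silhouette
width is computed with Euclidean distance; the smallest k attaining the
maximal width is returned ("lowest k yielding the highest silhouette").
By default clustering runs on all positive-eigenvalue axes, which preserves
the full Aitchison geometry; `axes = "first2"` restricts to the plotted
plane, since the literature does not always state which convention was
used.

**PERMANOVA.** One-factor, computed directly from the squared-distance
matrix: `SS_total = Σ d² / n` over all pairs, `SS_within` from group-blocked
sums, pseudo-F with (g−1, n−g) df, r² = SS_between/SS_total. Significance
permutes raw group labels (equivalent to permuting residuals in a
one-factor design). All permutation p-values in the package use the
add-one convention `(b + 1)/(m + 1)`, whose floor at 999 permutations is
0.001 — the floor value routinely reported with `adonis2`-style tests.
Because the observed labeling already provides the `+1`, a drawn
permutation that merely reproduces the observed partition of samples (the
identity or a relabeling of the same groups) is redrawn; otherwise the
attainable floor would depend on the chance of re-drawing the observed
partition (probability ≈ 1/1716 per draw at 7 + 7 samples), making "the
minimal p" ill-defined. The permutation null remains valid, which the
calibration tests verify. Pairwise PERMANOVA runs each pair's submatrix and
adjusts with Benjamini–Hochberg.

**Environmental vectors.** Each (centered) variable is regressed on the
first two ordination axes — the plane on which fitted arrows are displayed
— giving r² and a unit direction vector; significance permutes the variable
across samples with the same add-one convention. Samples with missing
values are dropped per variable with a warning; constant variables are
flagged and excluded. The implementation is cross-checked against
`vegan::envfit` r² in the tests.

## Temporal analysis

**Distance decay.** Pairwise Bray–Curtis dissimilarity on log(x+1)
abundances, partitioned into balanced variation (substitution of abundance
between vOTUs — the abundance analogue of turnover) and abundance gradient
(uniform gain/loss): with A the summed elementwise minima and B, C the two
surpluses, `d_bray = (B+C)/(2A+B+C)`, `d_balanced = min(B,C)/(A+min(B,C))`,
`d_gradient = d_bray − d_balanced`. The identity
`d_balanced + d_gradient = d_bray` is algebraic and tested to 1e-12. The
partition is applied to the same log-transformed abundances as the
dissimilarity it decomposes. When `min(B, C) = 0` one community is nested
in the other and the balanced component is defined as 0, which also covers
the degenerate case A = 0. Time distances are whole calendar months
(`12·Δyear + Δmonth`), exact for first-of-month sampling dates. The Mantel
test (Spearman by default — published work reports ρ; Pearson available)
correlates upper triangles and jointly permutes rows/columns of the second
matrix; the trend line drawn in decay plots is display only, inference
rests on the Mantel test.

**Dynamic classes.** Occupancy f = detections/timepoints classifies a vOTU
as sporadic (0 < f < 0.25), intermittent (0.25 ≤ f ≤ 0.75) or persistent
(f > 0.75). These boundary conventions — strict below, closed interval,
strict above — are the unique set reproducing the published integer bins at
14 timepoints (1–3, 4–10, 11–14), and the tests assert them for every
detection count. Never-detected vOTUs are excluded; per-timepoint class
percentages are computed among the vOTUs detected at that timepoint and
sum to 100.

## Annotation contrasts

The temperate call is evidence-based and inclusive at every published
threshold: lifestyle probability ≥ 0.95 on complete/high-quality genomes,
or any recombinase HMM hit with bit score ≥ 50. Auxiliary viral genes
(AVGs) are retained with annotation bit score ≥ 60, auxiliary score ≤ 3,
and no "V" flag. Contig labels propagate to vOTUs on the premise that
cluster members belong to one viral population: temperate if any member is
temperate, AVG categories as the union over members, host and quality from
the representative; the propagation is idempotent.

Per-sample category percentages count, among detected vOTUs, those in each
category. The denominator is a genuine open choice: this package defaults
to vOTUs with *any* assignment of the same annotation type (host-assigned
vOTUs for host contrasts, and so on), because host prediction covers only
~10–16% of vOTUs in practice and an all-vOTU denominator would compress
every host percentage toward zero; `denominator = "all"` is available.
Categories absent from a sample enter as explicit zeros, so effect sizes
include zeros. The group contrast is the difference of group medians of
per-sample percentages, with a two-sided rank-sum test per category and BH
adjustment over the categories that pass two filters: ≥ 5 vOTUs in at
least one group, and absolute median difference ≥ 0.1 (read as 0.1
percentage points on the 0–100 scale of the plotted effects). Filtered
categories are reported but flagged, never silently dropped. For strategy
and AVG contrasts — whose annotations derive from contigs in clusters —
vOTUs detected in both groups can be excluded first (`exclude_shared`);
the host contrast does not exclude them by default, following the narrower
published phrasing. Whether the exclusion also suits host contrasts is
left to the caller.

Exact conventions elsewhere: Wilcoxon tests enumerate exactly for untied
samples up to n = 25 per group and otherwise use the normal approximation
with tie and continuity correction; the Friedman statistic uses
within-subject mid-ranks with the standard tie correction, df = k − 1, and
Kendall's W = χ²/(n(k−1)); a fully tied matrix returns χ² = 0 and W = 0
rather than the NaN the raw statistic would give. Spearman correlations are
exact below n = 10 without ties. One consequence of exactness worth
recording: discrete null distributions make the attainable type-I level
fall below the nominal one (at 7 vs 7 the largest attainable two-sided
level under 0.05 is ≈ 0.038), so the calibration tests center their
binomial intervals on the attainable level computed from the null
distribution, not on 0.05.

## What the synthetic data emulate — and what they do not

The generator plants the structures the analyses are meant to recover, at
desk scale, from a single seeded generator per call (the caller's random
state is never touched; equal seeds regenerate bit-identical data).

* **Two ecosystems** (`simulate_two_ecosystems()`): a lagoon group with
  more vOTUs (default 400 vs 230, a ~1.75 richness ratio), higher nonzero
  abundance (lognormal with log-scale offset `log(abundance_fold)`,
  default fold 4.8), near-disjoint membership (`shared_fraction = 0.01`),
  Bernoulli detection (`detection_prob = 0.6`), 7 samples per group.
* **Time series** (`simulate_time_series()`): 14 monthly samples; each
  vOTU draws an occupancy class and a *contiguous* run of detections whose
  length falls in that class's bin. Contiguity serves two purposes: planted
  classes are recovered exactly by the classifier, and composition drifts
  monotonically in time, planting the distance-decay signal the Mantel test
  should find. Disturbances (default timepoints 1 and 8, emulating two
  episodic events) inject an extra cohort of sporadic vOTUs (15% of the
  base set) detected only at the event. The default occupancy mixture
  (0.65/0.30/0.05 sporadic/intermittent/persistent) is chosen so the
  *per-timepoint* class shares land in the published ranges (~27–50%
  sporadic, 37–60% intermittent, 9–14% persistent): each class contributes
  detections in proportion to its mean occupancy, so the vOTU-level mixture
  must be sporadic-heavier than the per-timepoint shares it produces.
* **Environmental driver**: one variable (`iz_percent`) is a blend
  `sqrt(r²)·z₁ + sqrt(1−r²)·noise` of the standardized first
  principal-coordinate axis of the generated community, with
  `env_signal_r2 = 0.5` by default (published significant fits lie at
  r² ≈ 0.4–0.5); the remaining variables are pure-noise decoys, making
  driver recovery quantitatively plannable.
* **Annotations** (`simulate_annotations()`): quality tiers, hosts (~30%
  assigned), planted temperate fractions realized through generated
  evidence (recombinase bit scores, lifestyle probabilities) rather than
  direct labels — so the calling rules themselves are exercised — and AVG
  categories with a planted lagoon enrichment of 5 percentage points in
  two categories, plus decoy gene rows the AVG filter must drop.

Not emulated: sequence content of any kind (no reads, contigs, FASTA),
real covariance among environmental variables, seasonality (the planted
temporal signal is monotone drift plus disturbances, not an annual cycle),
phylogenetic or host-range structure among vOTUs, and depth-dependent
detection (detection is independent of abundance). Passing tests therefore
demonstrate that the statistical machinery recovers known structure of
these kinds — not that real viral communities have that structure.

Distributional shapes are a modeling convenience, not a claim about data:
nonzero abundances are lognormal (`lognormal_mu = 0`,
`lognormal_sigma = 1.5`) under Bernoulli occupancy, chosen to match the
zero-inflated character that motivates the pseudo-count.

## Problem sizes and runtime choices

The test suite and the acceptance script run everything at desk scale,
chosen so the full suite completes in about a minute on one core:
generated communities of 60–630 vOTUs over 14 samples; 99–999 permutations
per test; calibration over 200–400 null simulations; oracle comparisons on
200 random clustering instances of up to 10 contigs; recovery rates over
20–50 seeds. These sizes are large enough that every planted effect sits
far from its decision boundary, and the published summary statistics that
are re-derived exactly (degrees of freedom, Kendall's W, occupancy bins,
carrier percentages) do not depend on scale at all.

## Known limitations

* The greedy centroid clustering is order-deterministic but, like all
  greedy clusterings, not globally optimal under any objective; it is the
  field's convention, not an optimum.
* PERMANOVA is one-factor only (no strata, no covariates), matching its
  use here.
* The envfit permutation test inherits the usual caveat that ordination
  axes are themselves data-derived; p-values are conditional on the
  ordination.
* `months_apart()` ignores days, which is exact for first-of-month
  sampling but coarse for irregular sampling dates.
* The AVG carrier percentage is reported to one decimal, matching the
  precision of the published quantity it mirrors.
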