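---
title: "Pathway-assisted clustering of breast cancer subtypes: methods and modeling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-assisted clustering of breast cancer subtypes: methods and modeling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(pathclust)
```

`pathclust` implements an integrative pipeline that relates breast cancer
subtypes through plasma proteome profiles: per-protein differential testing
against healthy controls, pathway-level summarization of the significant
proteins, four complementary distance metrics between subtypes, hierarchical
clustering, nearest-neighbor prediction of individual patients, and pathway
association networks. This vignette documents the statistical model, the
package's parameter choices and their rationale, the synthetic-data
generator's scope, and known limitations.

## Data model

Input is a proteins × sample-replicates matrix of log2 intensities plus an
annotation table with one row per injection: `sample_id`, `individual_id`,
`group` (`healthy`/`cancer`), `replicate`, and IHC receptor calls `ER`,
`PR`, `HER2`. Subtypes are assigned from receptor status:

| ER/PR              | HER2     | subtype   |
|--------------------|----------|-----------|
| ER+ or PR+         | negative | LuminalA  |
| ER+ or PR+         | positive | LuminalB  |
| ER− and PR−        | positive | HER2Plus  |
| ER− and PR−        | negative | BasalLike |
| undecidable (missing marker) |  | Unknown |

Intensities are quantile-normalized (`quantile_normalize()`, a wrapper over
`limma::normalizeQuantiles`) so per-injection global shifts are removed
before any statistic is computed.

Per-protein abundance in cancer samples follows the additive mixed model

$$ y_{ijr} = \mu + S_j + I_i + \varepsilon_{ijr} $$

with subtype fixed effects $S_j$ (sum-to-zero), a random intercept $I_i$
per individual, and residual $\varepsilon$. Because each individual carries
exactly one subtype, a subtype × individual interaction is unidentifiable
and is reported as `NA` rather than a number. For replicate-balanced designs
`fit_subtype_effects()` uses an exact closed-form REML solution (the
within-individual residual mean square estimates $\sigma^2_e$; the
between-individual mean square gives $\sigma^2_I$ by moment matching;
fixed effects are subtype means of individual means). Unbalanced designs
fall back to `lme4::lmer`. The closed form is bit-reproducible, has no
convergence failures, and is roughly two orders of magnitude faster —
which matters when the validation suite fits thousands of models.

## The variance-adaptive permutation test

Differential testing of a subtype against healthy controls uses a
permutation test whose statistic adapts to variance inequality. At the
observed labels *and at every resample*:

1. A two-sided F test compares the two group variances:
   $F = s_1^2 / s_2^2$, $p_F = 2\min\{P(F \le f), P(F \ge f)\}$ capped at 1.
2. If $p_F \ge \alpha_F$ (default 0.05) the pooled-variance t statistic is
   used (df $n_1+n_2-2$); otherwise Welch's t with Satterthwaite df.
3. The permutation p-value is the fraction of resamples whose t-test
   p-value is at most the observed one.

```{r}
x <- c(30.02, 29.99, 30.11, 29.97, 30.01, 29.99)
y <- c(29.89, 29.93, 29.72, 29.98, 30.02, 29.98)
f_variance_test(x, y)$p.value   # 0.114 >= 0.05, so the pooled branch is used
adaptive_t(x, y)$p.value
```

The permutation unit is the individual, not the injection: replicates are
collapsed to per-individual means before testing, so technical replication
cannot masquerade as biological sample size.

Design and numerical choices:

- **Estimator.** The default `estimator = "plain"` uses the plain fraction
  `count/B`, which can return exactly 0; `"plus-one"` gives the
  `(1+count)/(1+B)` variant that is never 0 and is the better choice when
  q-values will be computed from small `B`.
- **Exhaustive enumeration.** When `choose(n, n1) <= B` all label splits
  are enumerated (`utils::combn`), making the p-value exact; the unit tests
  verify equality against a brute-force oracle.
- **Tie tolerance.** Permuted p-values are compared to the observed one
  with a relative tolerance of `1e-9` (plus `1e-12` absolute). One-pass
  variance computation leaves last-ulp noise on permutations that are exact
  ties of the observed split; without the tolerance, exact ties would be
  dropped from the count and the exhaustive p-value would disagree with
  naive enumeration.
- **B.** The default is `B = 1000` per test, a desk-scale compromise; the
  granularity of the p-value is `1/B`, so raise `B` (e.g. to 100,000) for
  final analyses where q-values near the 0.05 cutoff matter.

## Three-step significance and pathway-protein matrices

Permutation p-values are adjusted by Benjamini–Hochberg (`bh_adjust()`),
and Storey–Tibshirani q-values are computed (`storey_qvalue()`): $\pi_0$ is
estimated on the grid $\lambda = 0, 0.05, \dots, 0.90$ with a cubic
smoothing spline (df 3) evaluated at the largest $\lambda$, clamped to
$(0,1]$. With fewer than 100 p-values the spline estimate of $\pi_0$ is too
unstable, so $\pi_0$ is fixed at 1 and the q-values reduce to BH.

Proteins are declared significant at three nested cutoffs — q < 0.2, 0.1,
0.05, coded 1, 2, 3 — and `declare_significant()` reports the expected
number of false positives (cutoff × set size) for each. For every subtype,
`pathway_protein_matrix()` builds the pathway × protein integer matrix
whose entry is the strictest cutoff level at which a pathway-member protein
is significant (elementwise maximum over the three per-cutoff matrices).
Pathway profiles count, per pathway, the proteins at or above a chosen
cutoff level (default 2, i.e. q < 0.1).

## Four distance metrics and clustering

Subtypes are compared by:

1. **Protein intensity**: 1 − Pearson correlation of the fitted subtype
   fixed-effect vectors.
2. **q-value**: 1 − correlation of the per-protein q vectors.
3. **Pathway profile**: 1 − correlation of the per-pathway significant
   counts.
4. **Distance score**: mean (or sum) of absolute entry differences between
   two subtypes' pathway–protein matrices. The mean mode is normalized by
   the matrix size and hence comparable across analyses; the sum mode
   reproduces the scale of published matrices.

`hierarchical_cluster()` wraps `stats::hclust` (average linkage by
default; single and complete supported) and exposes the merge table
directly; `to_newick()` serializes the dendrogram via `ape`. On the
shipped published five-subtype distance-score matrix:

```{r}
D <- example_subtype_distances()
tree <- hierarchical_cluster(D)
tree$merges[, c("height")]
to_newick(tree)
```

The two luminal subtypes merge first (height 151), then HER2Plus with
BasalLike (302), with Unknown joining last — the pattern the package's
acceptance tests pin down under all three linkages.

## Nearest-neighbor prediction

`predict_cohort()` matches each patient to the nearest subtype exemplar
under any of the four metrics. Ties are broken by the canonical subtype
order (LuminalA, LuminalB, HER2Plus, BasalLike, Unknown) and flagged.
Resubstitution is the default; leave-one-out exemplars are supported for
the intensity metric only, because rebuilding permutation-based exemplars
per held-out patient is quadratic in cohort size. Accuracy is reported both
over all five labels and restricted to the four known subtypes.

## Pathway association networks

`build_pathway_network()` connects pathways whose protein sets overlap,
with edge weight the Jaccard similarity $|P_i \cap P_j| / |P_i \cup P_j|$;
nodes carry the pathway size and the changed-protein count.
`select_top_pathways()` keeps pathways whose mean changed count across
subtypes strictly exceeds 5. Networks export to GraphML via `igraph`.

## The synthetic cohort generator

`generate_cohort()` simulates log2 intensities as baseline + planted
subtype effect + per-individual Gaussian effect + per-injection global
shift (shared across proteins within a column — exactly what quantile
normalization removes) + residual noise. Receptor status is derived from
the true subtype so that label assignment is round-trip recoverable.
Defaults emulate a cohort of 80 healthy controls and 80 patients
(24/15/10/19/12 across the five subtypes), 616 proteins, 2 replicate
injections; noise scales are fixed at $\sigma_\text{individual} = 0.4$,
$\sigma_\text{replicate} = 0.15$, $\sigma_\text{residual} = 0.3$ log2
units with baseline $\mathcal{N}(22, 1.5^2)$ and planted effect magnitude
1.5 — chosen once, a priori, to give realistic but recoverable signal, and
deliberately not adjusted afterwards.

`effect_plan_blocks()` plants the validation structure: the two luminal
subtypes share ~90% of a pool of differential proteins drawn from
luminal-active pathways, HER2Plus/BasalLike share another pool, ~10% leaks
across pairs, and Unknown gets its own pool. This makes the within-pair
distances small under every metric, which is the property the acceptance
suite checks.

The generator's scope is deliberately narrow. It does **not** emulate:
intensity-dependent (non-ignorable) missingness, heavy-tailed or
protein-correlated noise, batch structure beyond the per-injection shift,
shared-peptide ambiguity in protein inference, or any real biological
pathway topology — pathway databases are random protein sets with
controlled overlap. Conclusions about the pipeline's behavior on real
plasma data should be drawn accordingly.

## Problem sizes used in validation

Validation problem sizes are the package's own choices, scaled for a
single-CPU desk run: the clustering checkpoints use the printed 5×5 matrix;
permutation calibration uses 500 null proteins with two groups of 10 at
`B = 1000`; block-structure recovery uses 20 independent cohorts of 200
proteins, 40 pathways, 10 healthy + 20 patients over four subtypes at
`B = 500`, requiring every metric to pair the planted pairs in at least
95% of cohorts and nearest-neighbor accuracy to beat the majority-class
baseline.

## Limitations

- The per-patient q-value profile (`patient_qvalue_profile()`) tests one
  patient's handful of replicate injections against per-individual healthy
  means; exchangeability between a single individual's replicates and
  across-individual means does not hold, so these per-patient p-values are
  anti-conservative and many null proteins reach q = 0. The profiles
  separate shifted from null proteins in distribution (the tests assert
  stochastic dominance), but individual per-patient q-values should not be
  read as calibrated FDRs.
- `estimator = "plain"` can return a permutation p of exactly 0, which in
  turn yields q = 0; use `"plus-one"` when downstream analysis is
  sensitive to that.
- With the default `B = 1000`, p-value granularity (1/1000) limits how
  sharply the three q cutoffs can be distinguished for borderline proteins.
- The subtype × individual interaction is structurally unidentifiable in
  this design and is reported as `NA`, not estimated.
- Storey's $\pi_0$ is fixed at 1 below 100 tests; q-values then equal BH.

## End-to-end run

```{r}
design <- cohort_design(
  n_healthy = 10,
  subtype_counts = c(LuminalA = 6, LuminalB = 5, HER2Plus = 4, BasalLike = 5),
  n_proteins = 120, n_replicates = 2, seed = 42)
cfg <- pipeline_config(seed = 42, design = design, B = 200,
                       prediction = "resubstitution",
                       prediction_metric = "protein_intensity")
run <- run_pipeline(cfg)
run$analysis$distances$distance_score
run$analysis$prediction$summary
head(run$manifest)
```

Identical configurations produce identical manifests (md5 checksums of
every stage output), which is how the test suite pins determinism.
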