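---
title: "Methods: metabolomic chemotyping of submergence stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolomic chemotyping of submergence stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chemotypr implements the statistical chain used to chemotype rice coleoptiles
grown under normoxia versus complete submergence (hypoxia): untargeted GC-MS
abundance tables from a two-genotype × two-oxygen-condition × three-timepoint
factorial (3, 5 and 7 days after sowing, at least four biological replicates)
are preprocessed, ordinated, modelled per contrast with OPLS-DA, summarized by
metabolite set enrichment, and compared as correlation networks. This vignette
documents the models, the tunable parameters, the numerical choices, and what
the synthetic-data generator does and does not emulate.

## Preprocessing

The chain runs in this order, each stage advancing the table's state flag:

1. **Sample-median normalization** (`median_normalize()`): every sample's
   values are divided by that sample's median over non-missing metabolites,
   cancelling per-sample extraction/injection scale factors. Samples with no
   data or a zero median are rejected by name.
2. **Dixon outlier exclusion** (`dixon_filter()`): within every (genotype,
   condition, time) replicate group, each metabolite's most extreme value is
   tested with the two-sided r10 statistic Q = gap/range against the
   Rorabacher (1991) critical table (packaged for n = 3..30 at
   α ∈ {0.01, 0.05, 0.1}; other levels error rather than interpolate, so
   every decision is reproducible against the published table). At most one
   value is removed per metabolite per group; removed values become missing
   and are eligible for imputation. Outliers are handled at the level of
   individual values, not whole samples, because the downstream imputation
   rule treats single-replicate gaps as technical error. Groups smaller than
   3 are skipped with a warning, and a range at floating-point noise level
   (relative spread below 1e-12) counts as constant and is never tested.
3. **Log transform and autoscaling** (`log_autoscale()`): natural log, then
   per-metabolite centering to mean 0 and scaling to unit sample SD (n − 1
   denominator) over non-missing entries. Constant columns become all zeros
   rather than being dropped, so metabolite indices stay aligned. Because
   the Pearson correlation used later is location/scale invariant per
   metabolite, autoscaling does not change network construction.
4. **Group-aware KNN imputation** (`knn_impute()`): a missing cell is imputed
   only when the metabolite is observed in at least one other replicate of
   the same group (a compound absent from a whole group is left missing and
   flagged — its absence may be biology, not a technical error). The imputed
   value is the plain average of the k = 10 nearest metabolite rows, by
   Euclidean distance over mutually observed samples rescaled to the full
   sample count — the classic impute-by-similar-features scheme. All
   neighbours and distances are computed from a frozen snapshot of the
   incomplete matrix, so the result does not depend on the order in which
   cells are visited.

`preprocess_pipeline()` applies the stages in the order listed;
`impute_before_scale = TRUE` swaps the last two for sensitivity analysis.
Whether standardization preceded or followed imputation in the original
toolchain is not decidable from its description; the listed order is the
default.

## Ordination

`fit_pca()` is SVD-based PCA of the column-centered matrix (no missing values
accepted — imputation precedes ordination in this chain, which also makes the
result exactly reproducible, unlike iterative NIPALS with missing data).
Variance fractions are ratios of squared singular values over the full
spectrum; each component's sign is fixed so its largest-magnitude loading is
positive. `group_ellipse()` draws per-group 95% data ellipses from the 2×2
sample covariance with squared Mahalanobis radius `qchisq(level, 2)` — a
population-spread ellipse, not a standard-error-of-the-mean ellipse, which is
the common reading of score-plot "95% confidence" ellipses.

## OPLS-DA

`fit_oplsda()` implements two-class O-PLS with one predictive and (by
default) one orthogonal component — the structure used throughout the study.
With a single centered class vector y, the initial weight w ∝ Xᵀy is
unchanged by orthogonal deflation, so w ⊥ w₀ and t ⊥ t₀ hold exactly.
Diagnostics:

* **R²X** per component is the Frobenius share of the pre-deflation centered
  matrix captured by that component; **R²Y** is the explained share of y.
* **Q²Y** (`q2_cv()`) is 1 − PRESS/SS(y) over stratified 7-fold
  cross-validation with a deterministic, seed-logged fold assignment.
* **Permutation p** (`permutation_test()`) recomputes Q²Y under label
  permutations and uses the add-one estimator, so p is never exactly zero.
* **VIP** is the predictive-component form `sqrt(M)·|w|` (unit-norm w), so
  mean(VIP²) = 1. The classic multi-component PLS VIP reduces to exactly
  this expression when there is a single predictive component — the only
  case this package fits — so a second code path would be redundant.

### DAM selection

`select_dams()` keeps metabolites with VIP ≥ 1 (the community convention)
whose predictive loading passes a loading rule. The default rule thresholds
the *scaled* loading — the correlation between the metabolite and the
predictive scores, the `pcorr` quantity familiar from S-plots — at an
absolute 0.5. A relative top-quantile rule is also available
(`loading_rule = "quantile"`), but it selects a near-constant fraction of the
metabolite panel regardless of how strong the class difference is, which both
inflates false selections in weak models and makes the number of selected
metabolites uninformative about effect strength; the absolute rule lets the
DAM count genuinely shrink as a contrast fades, which is the behaviour the
intervarietal time course is meant to show. For the small per-timepoint
intervarietal models (n = 16), 0.5 is only ~1.9 null SDs of a score
correlation, so those analyses use `loading_cor_min = 0.6` (~2.3 null SDs);
at the full-design n = 48 the default 0.5 is already 3.4 null SDs.

Fold changes are computed from group means on the normalized (pre-log) scale,
where a ratio is meaningful. The contrast orientation is fixed globally:
hypoxia is the positive class, so "up" always means higher under submergence.

## Metabolite set enrichment

`msea_run()` ranks metabolites by predictive loading (ties broken
id-lexicographically and recorded) and walks the weighted Kolmogorov–Smirnov
running sum: hits add `|score|^1 / Σ|score|` and misses subtract `1/(N−m)`;
the ES is the extremum of largest magnitude. The accumulation is a plain
sequential sum, bit-reproducible against a position-by-position recomputation.
The null is fgsea-style random same-size member draws from the ranked
universe — not sample-label permutation, because the ranking comes from
loadings, not per-sample statistics. NES divides ES by the mean magnitude of
same-sign null scores; p is the add-one same-sign tail fraction; adjustment
is Benjamini–Hochberg across tested sets (`min_size = 3`, recorded in the
result's attributes). Because p is estimated from the same-sign half of the
null, two independent nulls of 10⁴ draws agree to well under 0.01 for the
small p-values that decisions rest on; mid-range p-values carry the usual
binomial Monte-Carlo error. `pathway_overlap_graph()` connects significant
sets that share members within the ranked universe, with |NES|, adjusted p
and direction as node attributes.

## Correlation networks

`build_network()` computes Pearson r with two-sided t-approximation p-values
for all metabolite pairs within a stratum, adjusts across all pairs by
Benjamini–Hochberg, and keeps edges with q < 0.05 (strict). The default
stratum is one network per genotype × condition, pooling the three time
points' replicates (n ≈ 12): with only four replicates per cell, essentially
no pair survives an FDR threshold over 68k tests, so the pooled reading of
"networks at each time point" is the one that yields the reported kind of
networks; a per-timepoint mode is available by adding `time_das` to the
stratum.

`network_metrics()` follows the Cytoscape NetworkAnalyzer conventions:
density 2E/(N(N−1)) over the full tested universe, unweighted diameter of the
largest connected component, heterogeneity = CV of the degree distribution
(population variance), and Freeman degree centralization
`(N/(N−2))(k_max/(N−1) − density)`. Edgeless networks use diameter 0,
heterogeneity 0 and an `NA` positive:negative ratio.

`network_dissimilarity()` compares networks by Bray–Curtis on aligned
node-degree vectors and by Jaccard distance on sign-agnostic edge sets (a
metabolite pair counts once regardless of correlation sign — "pairs of
metabolites" is pair identity). `ward_cluster()` applies Ward.D2
agglomeration (squared dissimilarities inside the merge cost; implementations
differ, so the variant is fixed and tested against exhaustive merge
evaluation); dendrograms export to Newick with merge heights as branch
lengths via `write_newick()`.

## The synthetic study generator

`simulate_dataset()` draws log-scale abundances under

log x_is = μ_i + α_i·[hypoxia] + β_i·g_s·shrink(t, cond) + γ_i·t̃·age(cond)
\+ Σ_f λ_if(cond)·z_fs + ε_is,

then exponentiates, multiplies by a per-sample lognormal scale factor,
injects multiplicative outlier spikes and MCAR missingness (an optional
left-censoring mode exists). Effects live on the log scale so the
preprocessing chain linearizes them. Defaults define the study conditions:

| parameter | default | what it encodes |
|---|---|---|
| `n_metabolites`, design | 370; 2×2×3×4 | panel size and factorial layout |
| `condition_effect_sd` | 2.0 | hypoxia effects on the 40 DAMs (log scale; typical ~e²-fold responses, so the oxygen axis dominates PC1) |
| `genotype_effect_sd`, `n_genotype_mets` | 0.5 on 25 metabolites | concentrated, modest varietal differences (~1.6-fold), weak relative to the oxygen effect |
| `genotype_shrink_rate` | 0.45 per time step under hypoxia | varietal differences level out during submergence |
| `age_effect_sd`, `age_hypoxia_factor` | 0.05, ×0.3 | a minor developmental axis, damped under hypoxia (arrested development) |
| `n_latent_factors`, `block_size`, `factor_loading_sd` | 6 × 12, 0.68 | co-regulated modules with within-block r ≈ 0.97 |
| `sign_mixing_fraction` | 0.1 / 0.3 | sign flips that drive the positive:negative edge-ratio drop under hypoxia |
| `rewire_fraction` | 0 / 1⁄3 | hypoxia swaps a third of each block's members for condition-specific alternates, changing which pairs are co-regulated |
| `noise_sd` | 0.12 | residual CV of derivatized GC-MS with an internal standard |
| `outlier_prob`, `outlier_multiplier` | 0.002, ×20 | sporadic single-value integration errors |
| `missing_prob` | 0.02 | sparse missingness |
| `sample_scale_sd` | 0.2 | per-sample extraction/injection scale |

These values were fixed once, from a power analysis of the joint
requirements, before the recovery tests were written: the Dixon test operates
on the (right-skewed) normalized scale, so its false-positive rate stays near
the nominal α only while within-replicate-group spread stays below roughly
0.7 log-units — which bounds `factor_loading_sd` from above — while edge
recovery at q < 0.05 from 12-sample strata bounds the within-block
correlation (hence `factor_loading_sd/noise_sd`) from below; 0.68/0.12
satisfies both. Latent factors are drawn per sample, i.i.d.: batch-structured
variants (factor levels shared within replicate groups or time points) were
rejected because they either confound the two-cell intervarietal contrasts
or, with only three time points, cannot carry six mutually independent
factors. Sign flips alone do not change which metabolite *pairs* are
connected, so without membership rewiring the sign-agnostic Jaccard
comparison could never separate hypoxia from normoxia networks; the
`rewire_fraction` term supplies the composition change that submergence
produces in real data, and the ground truth records block membership per
condition accordingly.

What the generator does **not** emulate: chromatographic artifacts and
retention-index drift, metabolite identity ambiguity, intensity-dependent
variance (beyond optional left-censored missingness), inter-batch drift, and
correlated DAM/module structure (planted DAMs, genotype responders and block
members are disjoint sets, so recovery metrics are unambiguous). Passing
recovery tests therefore show that the chain detects the planted effect
classes at realistic effect sizes and noise — not that it is robust to every
artifact of real GC-MS data.

## Problem sizes and statistical formulations used by the test suite

The recovery tests run the full default design (48 samples × 370
metabolites); orchestration tests use a reduced panel (60–80 metabolites, 2
latent blocks) that preserves every structural feature. Outlier recall is
estimated with the spike magnitude at its default but an elevated spike rate
(1%), giving ~180 events instead of ~35 for a stable rate estimate. The
intervarietal "leveling" pattern is assessed as: mean predictive variance
(over three generator replicates) maximal at 3 DAS and lower at 7 DAS than at
3 DAS, and likewise for the DAM count — with eight samples per genotype per
time, the middle time point rides the small-n fit floor, so per-step
monotonicity of a single draw is not a property these study conditions can
guarantee. Null-calibration checks (permutation-p uniformity, enrichment
padj rate, false-edge rate) use seeded replicate batches sized so that their
pass thresholds sit several Monte-Carlo SDs from the expected value.

## Known limitations

* Dixon's r10 assumes approximate normality within replicate groups; on the
  right-skewed normalized scale its false-positive rate runs slightly above
  nominal for high-variance metabolites. Removed values are imputed rather
  than lost, which bounds the damage, but heavy-tailed panels deserve a
  log-scale look before trusting exclusion counts.
* Q²Y from 7-fold CV on 16-sample models is noisy; the permutation test, not
  Q²Y's point value, is the guard against overfitting claims.
* The enrichment null draws random member sets, so strongly overlapping sets
  are tested marginally, not jointly.
* Network edges are marginal Pearson correlations; no conditional
  independence or community structure is inferred.
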