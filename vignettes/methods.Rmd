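---
title: "Methods: DI-HRMS panel discovery, harmonization and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DI-HRMS panel discovery, harmonization and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and study design

`metabpanel` implements the analysis chain for an untargeted
direct-infusion high-resolution mass-spectrometry (DI-HRMS) serum
metabolomics study of severe aortic stenosis (AS): healthy controls versus
AS patients, with a paired arm sampled before and after aortic valve
replacement (AVR). Because direct infusion has no chromatographic
separation, a peak is characterized by its m/z alone; acquisition is in
technical triplicate; and the cohort is split over two MS runs that share
the AS-before-AVR group. The package covers everything downstream of peak
picking: triplicate averaging, ppm-window annotation, anchored Z-score
harmonization, gradient-boosting panel discovery with stability selection
and permutation validation, paired/reversal/correlation statistics, and an
offline metabolite-to-gene evidence join.

The original cohort (9 controls, 10 AS patients) is not publicly
deposited, so the package ships a first-class synthetic-study generator
with known ground truth; all validation is property-based against that
ground truth.

# Annotation

Technical triplicates are averaged arithmetically per sample. A peak with
observed m/z $x$ matches a database record with monoisotopic mass $m$ iff

$$\left| \frac{x - \delta - m}{m} \right| \cdot 10^6 \le \tau,$$

with tolerance $\tau = 2$ ppm by default and a single configurable adduct
offset $\delta$ (default 0, i.e. direct mass matching; set
$\delta = 1.007276$ Da to read peaks as [M+H]+ against neutral masses).
The source protocol does not state polarity or adducts, so direct matching
is the default rather than an inference. The theoretical mass sits in the
denominator; this convention is asymmetric at the sub-ppb level and is
stated rather than assumed.

All matches within the window are retained. Isobaric records produce a
composite label joining the metabolite names with `"/"` in ascending
alphabetical order; ties in ppm never discard a match. Peaks matched by no
record are excluded from downstream matrices but counted and listed —
direct infusion analyses only annotated metabolites. When two distinct
peaks receive the same composite label (both members of an isobar pair
generate a peak that matches the whole pair), labels are disambiguated
with an `" (k)"` suffix in ascending m/z order so feature identities stay
deterministic.

# Harmonization by anchored Z-scores

The two runs are made comparable by standardizing each feature within each
run against the group measured in every run (AS before AVR):

$$z = \frac{x - \bar{x}_{\text{anchor}}}{s_{\text{anchor}}},$$

so Z-score units are standard deviations away from the anchor group's
mean. The sample standard deviation ($n-1$ denominator) is used; the
source protocol does not specify, so this is a stated choice. Features
with zero anchor variance are dropped with a warning — Z-scoring is
undefined there and imputation would fabricate cross-run comparability.

Two choices deserve emphasis:

* **Log scale.** Peak intensities are approximately log-normal (the
  generator draws them with a between-subject SD of 0.5 on the log10
  scale, a factor of ~3). The pipeline therefore standardizes **log10
  intensities**: Z-scores of raw log-normal values are so skewed that
  per-feature t-tests lose essentially all power at n = 9 vs 10. The
  `anchor_zscore()` operation itself is scale-agnostic and linear — its
  affine-invariance contract (multiplying a run's input by a positive
  constant and shifting any feature by a constant leaves Z-scores
  unchanged) is tested exactly as stated.
* **Duplicate anchor samples.** The anchor subjects appear in both runs.
  After merging (an inner join on feature labels, dropped features
  counted), both copies are retained under `"<sample>@<run>"` column
  names, and every two-group contrast is taken within the run containing
  both groups: the run-1 copy serves the control-vs-AS contrast, the
  run-2 copy the pre-vs-post contrast. This keeps each contrast free of
  cross-run artifacts. Which copy fed which analysis in the source study
  is unstated; this rule is explicit, not inferred.

# Panel discovery

The discriminative model is gradient boosting with logistic loss and
depth-limited regression trees, written in compiled code in this package
(no boosted-tree library is assumed present). Splits and leaf weights use
the second-order formulation with L2 penalty $\lambda = 1$: leaf weight
$-G/(H+\lambda)$, split gain
$\tfrac12\left(G_L^2/(H_L+\lambda) + G_R^2/(H_R+\lambda) -
G^2/(H+\lambda)\right)$, where $G, H$ are gradient/Hessian sums. Feature
importance is the total split gain per feature.

The evaluation protocol:

1. **Repeated stratified hold-out.** Ten repetitions of a stratified
   80/20 split. On each training partition, 5-fold stratified
   cross-validation picks hyperparameters from a small fixed grid
   (depth {2, 3} × trees {100, 300}, learning rate 0.1); the model is
   refit on the whole training partition and scored by ROC AUC (computed
   rank-based, hence invariant to monotone score transforms) on the
   held-out 20%. Test AUCs are averaged into the final test ROC AUC.
2. **Ensemble importance.** Per repeat, importances are averaged over the
   refit model *and* the winning configuration's five CV fold models —
   the "combination of multiple gradient boosting classifiers" is taken
   literally as an ensemble whose members all contribute evidence.
3. **Column subsampling.** Each tree sees a random fraction of features
   (`colsample = 0.05` by default, never fewer than 50 features per tree
   so small problems are not starved). With n = 19 and many mutually
   informative metabolites, a deterministic greedy fit concentrates all
   gain on one representative per signal cluster; per-tree feature
   subsampling is the standard randomization that lets correlated
   discriminative features share importance — fully deterministic fits
   (`colsample = 1`) recover fewer than half the planted features in the
   package's own simulations, randomized fits about four in five, against
   a univariate-screening information ceiling of roughly nine in ten. It
   is also in the spirit of randomized stability selection, which
   deliberately perturbs the selector.
4. **Stability selection.** 100 stratified subsamples of 80% of the
   samples, drawn without replacement, each refit with fixed
   hyperparameters (depth 2, 300 trees); per draw, the features with
   nonzero importance ranking in the top `2K` are marked selected. A
   feature's frequency of selection measures the robustness of its
   importance. The original stability-selection constants are unstated;
   these defaults are documented and configurable, and frequencies are
   reported raw rather than thresholded.
5. **Composite ranking.** Score = mean ensemble importance × stability
   frequency, rescaled so the best feature reads 100% ("relative
   variable importance"). The top K = 30 features form the panel, with a
   deterministic tie rule (score descending, then name ascending).
6. **Permutation validation.** Labels are reshuffled uniformly at random
   (1000 times by default) with profiles intact, and the hold-out AUC
   pipeline is re-run per reshuffle. The empirical p-value uses the
   add-one estimator $(1 + \#\{A_{\pi} \ge A_{\text{obs}}\})/(N+1)$, so
   it is never zero. For exchangeability between the observed statistic
   and the null draws, the observed AUC is recomputed under the same
   reduced settings as the permutations (one repetition with the fixed
   hyperparameters by default; the full 10-repeat, CV-selected protocol
   is available via `perm_repeats` / `perm_cv_select`). Note the
   resolution limit: with 19 subjects the test partition holds 4
   subjects, the null AUC takes 5 discrete values, and a single-repeat
   permutation test cannot reach p below about 1/6 even under perfect
   separation; the full-repeat mode averages away that discreteness.

# Downstream statistics

* **Group tests.** Welch's two-sided t-test per feature on Z-scores
  (robust to unequal variance at n = 9 vs 10; Mann-Whitney available by
  flag — the source figure does not name its test), BH-adjusted across
  all annotated features, reported as $-\log_{10}(p_{\text{adj}})$ with
  the p floored at the smallest representable double so the logarithm is
  finite, flagged when it happens.
* **Paired tests.** One-tailed paired t-test on post − pre differences
  per feature, closed form $t = \bar d / (s_d/\sqrt n)$ on complete
  pairs. The tested direction per feature is *change toward the control
  mean* (the sign of control mean − case-pre mean): the analysis
  question is post-intervention normalization. Zero-variance differences
  give p of 0 or 1 by sign and are flagged.
* **Reversal classes.** A feature is `reversal_toward_control` iff its
  paired change is significant and opposes its pre-intervention deviation
  from controls; a significant change in the deviation's direction is
  `further_deviation` (using the complement of the one-tailed p — exact
  for the continuous t distribution); anything else is
  `no_significant_change`. The classification operates on Z-scores and is
  therefore invariant to positive rescaling of the intensities.
* **Clinical correlations.** Spearman correlation (average ranks on
  ties) of each panel feature with LVMi (left-ventricular mass indexed to
  body surface area, g/m²) and MEEi (indexed myocardial external
  efficiency), over pooled control + case-pre samples; BH adjustment
  across the whole feature × covariate family; significance at adjusted
  p < 0.1. The effect size is reported as the simple-regression R²
  (identically the squared Pearson correlation) next to Spearman's rho,
  because the source analysis mixes "linear regression" and "Spearman"
  wording — both readings are computed side by side rather than choosing
  one.
* **BH families.** The group tests adjust across all annotated features;
  the correlation analysis adjusts across the panel × covariate tests.
  The two families are deliberately separate and explicit in the
  reports.

# Gene evidence join

Live pathway-database queries are replaced by an offline join against a
user-supplied metabolite → gene mapping table and a differential
expression table (gene, log2 fold change, p) — reproducibility over
liveness. Matching is case-insensitive, composite labels are expanded so
`"A/B"` matches rows for either member, and gene symbols are uppercased
with whitespace stripped (no alias resolution). Direction labels: `up` if
p < 0.05 and log2FC > 0, `down` if p < 0.05 and log2FC < 0, else `ns`;
genes absent from the expression table are flagged unmeasured. A small
synthetic fixture bundling three published example values (NOS1 +0.71 up,
NOS3 −0.8 down, AKR1B10 +0.89 up) is included for pass-through checks.

# The synthetic-study generator

The generator states a world and keeps it fixed:

* 9 control and 10 case subjects; cases contribute pre samples to both
  runs (same subject-level values, independent technical noise and a
  run-2 batch factor) and post samples to run 2 only.
* log10 intensities are Gaussian with between-subject SD 0.5 around a
  per-feature baseline drawn from U(4, 7) — positive, right-skewed raw
  intensities typical of MS counts. These distributions are generator
  choices; the source protocol states none.
* Planted discriminative features (default 30, matching the panel size
  the study reports) are shifted by `effect_size × 0.5` log10 units with
  a random sign; `effect_size` is Cohen's d by construction. Reversing
  features (default 14 of 30, the study's reported reversal count) have
  their case-post mean back at the control mean; the other planted
  features keep their case-pre mean. Pre and post draws are independent
  (no subject random effect beyond the group mean) — a simplification
  that makes the paired-difference SD $\sqrt2 \cdot 0.5$ log10 units.
* Technical triplicates multiply each intensity by
  $1 + \mathrm{CV}\cdot\varepsilon$, $\varepsilon \sim N(0,1)$, CV = 0.1
  by default; run 2 applies a per-feature multiplicative batch factor
  with SD 0.2 on the log10 scale.
* Each database record generates exactly one peak at its mass perturbed
  within ±1.5 ppm (drawn once, shared by both runs — direct infusion
  measures the same ion either way); 5% decoy peaks sit >5 ppm from
  every database mass to exercise the unannotated path. The database
  itself has base masses mutually >10 ppm apart plus a configurable
  fraction of isobar twins within ±1 ppm, giving exactly
  `floor(fraction·n)` two-membered isobar groups.
* LVMi and MEEi are linear in a linked planted feature's standardized
  log-intensity plus Gaussian noise, mixed to a target Pearson r (0.7 by
  default, roughly the R² ≈ 0.5 strength the study highlights), then
  placed on clinical scales (LVMi ≈ 100 ± 30 g/m²).

What a green test does **not** establish: the generator has no isotope
envelopes, no adducts, no correlated metabolite modules (every non-planted
feature is independent noise), no missingness, and technical noise is
homoscedastic on the log scale. Recovery results therefore bound the
pipeline's correctness, not its field performance on real serum.

# Numerical and engineering choices

* All randomized operations take explicit seeds; per-stage seeds are
  derived from the global seed by stage-name hashing (kept below 2³¹),
  so any stage reproduces in isolation. RNG state is always restored.
* The boosting fit is deterministic for `colsample = 1`: features are
  scanned in column order, cut points at midpoints between distinct
  sorted values, strictly-greater gain wins, no cut between tied values.
* Degenerate inputs error early and specifically: absent anchor group,
  classes lost by stratification, empty databases or mappings, p-values
  outside [0, 1], all-zero importances.
* The run manifest contains only deterministic content (config hash with
  the output path excluded, seed, per-stage file checksums, package
  version); wall-clock timings go to the run log so manifests from
  identical configurations are byte-identical.
* Fixture TSVs print doubles with 17 significant digits, so files
  round-trip losslessly and are byte-identical for a fixed seed.

# Selection bias in reversal counts

Panel membership is earned by case/control separation. A noise feature
that enters the panel did so because its case-pre samples happened to
deviate from controls; its post-intervention samples, unselected, regress
to the mean, so the paired test sees an apparently genuine change "back
toward control". Reversal counts over a selected panel are therefore
biased upward for features without a real effect — visible in the
generator, where unplanted panel members are classified as reversals well
above the nominal false-positive rate. Interpret reversal fractions of a
discovered panel with this in mind; the package's recovery tests
deliberately score only planted features, where ground truth is known.

# Known limitations

* The permutation p-value's resolution at the cohort's size is limited by
  the 4-subject test partition (see above); report it together with the
  observed AUC, never alone.
* Stability-selection frequencies are reported raw; no error-control
  threshold is claimed.
* Composite isobar labels make feature identity ambiguous by design;
  gene mapping expands them, but group statistics treat a composite as a
  single feature.
* The acceptance suite scales some simulations down for runtime (noted in
  the tests); the properties checked do not depend on the scaled sizes.
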