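---
title: "Methods: DNA methylation biomarkers of anti-TNF response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNA methylation biomarkers of anti-TNF response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scientific setting

`methresp` implements an epigenome-wide association workflow for predicting
therapy response in rheumatoid arthritis from whole-blood DNA methylation
measured on Illumina EPIC-style arrays. Patients are classified as responders
or non-responders to an anti-TNF biologic from their DAS28 disease-activity
trajectory; the analysis then asks (i) whether blood cell composition differs
between the groups, (ii) which CpG sites and genes are differentially
methylated after adjusting for clinical covariates, and (iii) whether a
sparse CpG panel can prospectively classify response.

Because real cohorts of this kind are controlled-access, the package ships a
seeded synthetic-cohort generator with full ground truth. Every downstream
method is validated against that truth or against independent statistical
oracles; the package is a methods artifact, not a data release.

# The synthetic cohort generator

`generate_cohort()` draws, per patient:

* **Cell mixtures.** Proportions of six leukocyte types (B, CD4T, CD8T,
  monocytes, neutrophils, NK) from a Dirichlet with mean
  (.05, .12, .08, .08, .60, .07) — typical whole blood — and total
  concentration 50, giving realistic inter-individual spread. Betas on the
  deconvolution probes are the mixture of sorted-cell reference profiles
  from `generate_reference_profiles()`.
* **Planted response effects.** `n_informative` CpGs (default 20) receive a
  logit-scale shift of alternating sign (default `delta_logit = 0.4`) in
  responders. On the beta scale this corresponds to group differences of
  roughly 0.04–0.10 depending on the baseline level, matching the magnitude
  of differences reported for blood EWAS of treatment response.
* **SNP-affected probes.** `n_snp_probes` tri-modal probes with cluster
  means 0.05 / 0.50 / 0.95 under Hardy–Weinberg genotype frequencies at
  allele frequency one half — the signature that gap hunting must find.
* **Covariates.** Sex, smoking, methotrexate co-therapy and age with
  group-specific prevalences (configurable via `covariate_assoc`);
  `covariate_effects` can additionally plant covariate-driven methylation
  shifts to create genuine confounding for robustness checks.
* **DAS28 trajectories.** Baseline scores around 4.8 (SD 1.2); follow-up
  drawn around 2.6 (responders) or 3.8 (non-responders) and redrawn until
  consistent with the intended label under the classification rule, so
  labels are exactly recomputable from the emitted columns.
* **Noise.** Logit-normal measurement noise, default `noise_sd = 0.15`.
  This is a *technical replicate* noise scale: on the M scale, EPIC
  replicate differences are of this order. It was chosen a priori (before
  any test expectations were frozen) over the larger biological-variation
  scale (~0.4), which would wash out the genotype clusters that gap hunting
  is defined to detect. With `noise_sd = 0` the cohort equals its mixture
  means bitwise, which several exactness tests rely on.

The whole cohort is a pure function of `generator_config()$seed`.

# Response labels

`classify_das28()` applies the EULAR-style rule: responder if follow-up
DAS28 < 3.2 **or** decrease ≥ 1.2; non-responder if follow-up > 5.1 **or**
decrease < 0.6. The two rules can both fire (a 1.3-point drop that still
leaves DAS28 at 5.3) — such cases are surfaced as `"conflict"` rather than
silently resolved, and cases where neither fires are `"indeterminate"`.
Boundary semantics are exactly as printed: ≥ 1.2 is inclusive, the 3.2/5.1
cuts and the 0.6 decrease are strict.

# Preprocessing

Betas are converted to M-values, `log2((β + o)/(1 − β + o))`, with an
explicit offset argument (`o = 0` is exact and errors on boundary betas;
the pipeline default is `1e-6`). Allosomal probes are removed to avoid
sex-driven signal. `gap_hunt()` sorts each probe's betas, cuts at gaps
larger than `threshold = 0.3`, discards clusters smaller than
`min_group_fraction`, and flags probes with two or more remaining clusters
as SNP-affected; flagged probes are reported and can optionally be dropped.

# Cell-type deconvolution

`estimate_proportions()` solves, per sample, the non-negative least-squares
problem `min ||R w − b||², w ≥ 0` (via `pracma::lsqnonneg`). The sum-to-one
constraint is *not* imposed during optimization; normalized proportions are
computed afterwards, and the unconstrained weights are retained.

`compare_proportions()` tests composition differences between response
groups with a two-way ANOVA of proportion on group and cell type — but with
two necessary refinements over the textbook fixed-effects version:

1. **Split-plot error strata.** The six proportions of one sample are
   correlated (they sum to one) and each sample contributes all six cell
   types. The model is `aov(y ~ group * celltype + Error(sample))`: the
   group main effect is tested against between-sample variation, cell type
   and the group-by-cell-type interaction against the within-sample
   residual. A plain two-way ANOVA on the same data is badly
   anti-conservative (empirical interaction type-I error ≈ 0.11 at
   α = 0.05, group p-values far from uniform under the null).
2. **Variance stabilization.** Proportions near 0 (B cells) and near 0.6
   (neutrophils) have very different variances; `asin(sqrt(p))` equalizes
   them. With both refinements, null simulations give uniform p-values for
   both the group and interaction terms (Kolmogorov–Smirnov p ≈ 0.6–0.9)
   while a planted 0.1 CD4T shift is detected in > 95% of replicates.

Note one structural fact: on row-normalized proportions the group main
effect is exactly zero by construction (both groups' proportions sum to
one), so composition differences appear in the interaction term. The
`use = "raw"` option runs the same ANOVA on the unconstrained NNLS weights,
where a group main effect is meaningful.

# Differential methylation

`fit_dm()` fits per-CpG ordinary least squares of the M-value on an
intercept, the response indicator and the clinical covariates (age, sex,
smoking, methotrexate), sharing one design across probes so the normal
equations are solved once. Each probe keeps its own residual variance — no
moderation across probes — and the response coefficient is tested with a
t-test on the residual degrees of freedom. The beta-scale group difference
is reported alongside for interpretability, with
hyper-/hypomethylation direction. `covariate_robustness()` refits a panel
with and without covariates, the check that an association is not explained
by treatment co-exposures.

# Gene-level aggregation

`annotate_probes()` assigns each probe to the nearest gene within 20 kb
(inclusive), breaking exact distance ties by gene-midpoint distance and
then lexicographic symbol so annotation is deterministic.
`brown_combine()` extends Fisher's statistic `ψ = −2 Σ ln p` to correlated
tests: `E[ψ] = 2k`, `Var[ψ] = 4k + 2 Σ cov`, with pairwise covariances
approximated from score correlations by the Kost–McDermott polynomial
`3.263ρ + 0.710ρ² + 0.027ρ³` (clipped to [0, 4]), and ψ referred to a
scaled chi-square with `f = 2E²/Var` effective degrees of freedom. It
reduces exactly to Fisher at zero correlation, to the input p-value at
k = 1, and to the input p-value for perfectly correlated identical tests.
`gene_level_scan()` estimates the correlation matrix from the probe
M-values; simulations with within-gene correlation 0.6 show Brown holds the
type-I error near α where naive Fisher roughly doubles it.
`regional_profile()` summarizes a gene's beta-scale differences with a
degree-1 loess curve and pointwise standard errors on a 200-point grid.

# The stability-selected classifier

`stability_classify()` runs the full prognostic workflow:

1. **Split.** Stratified 70/30 train/test split
   (`round(fraction · n_class)` per class; 92 samples at 49/43 give
   64 train / 28 test).
2. **Stability selection.** 100 resamples over 5-fold stratified
   cross-validation; 100 resamples at 5 folds imply
   `ceiling(100/5) = 20` repeats of the fold assignment, which is how
   `cv_repeats` is derived in `boost_config()`. Each resample holds out one
   fold, appends a freshly drawn standard-normal noise column (a
   permuted-real-feature variant is available), fits gradient-boosted trees
   (200 trees, depth 3, learning rate 0.1, row subsample 0.8 — fixed
   defaults so runs are reproducible), and reads gain importances. A
   feature is *selected* in a resample when its gain strictly exceeds the
   noise column's; the full importance order feeds a pairwise win matrix,
   and the held-out fold yields a per-resample AUROC.
3. **Aggregation.** Consensus order by Copeland score of the win matrix
   (ties by mean importance, then feature id). Panel membership: a paired
   one-sided sign-flip permutation test of each feature's per-resample
   importance margin over the noise column, Benjamini–Hochberg adjusted at
   `aggregation_alpha` across the features the noise rule ever retained
   (features never selected are discarded a priori — they cannot be panel
   candidates, and keeping them in the BH family would only dilute it).
4. **Final model.** Boosted trees retrained on the training set restricted
   to the panel, evaluated once on the untouched test set. AUROC is the
   midrank Mann–Whitney statistic; `roc_points()` gives the monotone curve.

The test set never influences selection: corrupting held-out rows or labels
changes neither the stability result nor the panel, bit for bit.

# Limitations

* **Panel q-values are anti-conservative in high dimensions.** The
  sign-flip test treats per-resample margins as independent, but all
  resamples reuse the same training samples; a feature that is
  in-sample-predictive by chance beats the (rarely used) noise column in
  nearly every resample and reaches the permutation floor. On permuted-label
  data with 1,000 features the panel is bimodal — empty or several dozen
  features — depending on whether the number of floor-level features
  crosses the BH threshold. Treat the panel as a screening/ranking device
  and rely on the held-out AUROC (which stays near 0.5 under the null) for
  validation; see `?aggregate_pairwise`.
* The generator's noise is logit-normal and homoscedastic per probe;
  real arrays show probe-type-specific error structure.
* Brown's method relies on the Kost–McDermott approximation, which is
  accurate for moderate correlations but still an approximation; the
  non-PSD correlation warning should not be ignored.
* Sample-size arithmetic (rounding per class) matches the reference
  workflow but differs by ±1 from other common conventions.

# Reproducibility

Every stochastic component is a pure function of an integer seed:
the generator (`generator_config()$seed`), the classifier
(`boost_config()$seed`, with per-resample seeds derived as documented in
`run_stability_selection()`), and the pipeline (`pipeline_config()$seed`).
`run_pipeline()` records output checksums in `run_report.json`;
`verify_run()` re-checks them. The `analysis/` scripts (numbered, thin)
reproduce the full workflow end to end, and `scripts/acceptance.R` writes
the headline quantities for any seed.
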