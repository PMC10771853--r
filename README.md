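# methresp

Peripheral-blood DNA methylation classifiers of anti-TNF response in
rheumatoid arthritis.

`methresp` implements a complete epigenome-wide association (EWAS) workflow
for predicting response to an anti-TNF biologic from whole-blood Illumina
EPIC-style methylation data:

* a **seeded synthetic-cohort generator** with full ground truth — blood
  cell mixtures drawn from a Dirichlet over six leukocyte types, planted
  response-associated CpGs, tri-modal SNP-affected probes, clinical
  covariates with group-specific prevalences, and DAS28 disease-activity
  trajectories consistent with the response labels;
* **preprocessing**: beta/M-value conversion with explicit offset handling,
  allosome filtering, and *gap hunting* to flag SNP-affected probes from
  multi-modal beta distributions;
* **cell-type deconvolution** by non-negative least squares against
  sorted-cell reference profiles, with a variance-stabilized split-plot
  ANOVA comparing composition between response groups;
* **differential methylation**: covariate-adjusted per-CpG ordinary least
  squares on M-values (age, sex, smoking, methotrexate), with beta-scale
  effect sizes and a covariate-robustness check;
* **gene-level aggregation** of correlated per-probe p-values by Brown's
  method (Kost–McDermott covariance approximation), nearest-gene annotation
  within 20 kb, and loess-smoothed regional methylation profiles;
* **response labeling** from DAS28 trajectories under the EULAR-style rule
  (responder if follow-up < 3.2 or decrease ≥ 1.2; non-responder if
  follow-up > 5.1 or decrease < 0.6), with cohort characteristics tables;
* a **stability-selected gradient-boosting classifier**: stratified 70/30
  split, 100 resamples over repeated 5-fold stratified cross-validation,
  per-resample noise-probe feature retention, Copeland rank aggregation with
  a paired sign-flip permutation test and Benjamini–Hochberg control, and a
  final panel model evaluated once on the untouched test set.

Real cohorts of this kind are controlled-access, so the package validates
every method against its own generator's ground truth or against independent
statistical oracles. See the vignette
(`vignettes/methylation-response-workflow.Rmd`) for the methods and their
rationale, including known limitations of the panel permutation test.

## Worked example

```r
library(methresp)

## 1. Simulate a small cohort with known ground truth
refs <- generate_reference_profiles(n_probes = 120,
                                    n_discriminating_per_type = 15, seed = 7L)
cfg <- generator_config(seed = 7L, n_samples = 60, n_probes = 800,
                        n_informative = 10, n_snp_probes = 8)
cohort <- generate_cohort(cfg, refs)
table(cohort$sheet$response)
#> non_responder     responder
#>            28            32

## 2. Labels are exactly recomputable from the DAS28 columns
lab <- label_response(cohort$sheet$das28_baseline, cohort$sheet$das28_followup)
all(lab$response == cohort$sheet$response)
#> [1] TRUE

## 3. QC: find SNP-affected probes by gap hunting, then drop them
gaps <- gap_hunt_matrix(cohort$beta)
flagged <- gaps$probe_id[gaps$flagged]
identical(sort(flagged), sort(cohort$truth$snp_probe_ids))
#> [1] TRUE
beta <- cohort$beta[setdiff(rownames(cohort$beta), flagged), ]

## 4. Cell-type deconvolution against the sorted-cell reference
props <- estimate_proportions(beta[rownames(refs), ], refs)
mean(abs(props$proportions - cohort$truth$true_cell_proportions))
#> [1] 0.005610063
compare_proportions(props, cohort$sheet$response)$anova
#>             term        stratum        sumsq  df          F       p_value
#> 1          group between-sample  0.001253466   1   2.791909  1.001293e-01
#> 2      Residuals between-sample  0.026039904  58         NA            NA
#> 3       celltype  within-sample 19.410134980   5 647.375856 5.553708e-155
#> 4 group:celltype  within-sample  0.038961844   5   1.299474  2.641020e-01
#> 5      Residuals  within-sample  1.739001878 290         NA            NA

## 5. Covariate-adjusted differential methylation on M-values
m <- beta_to_m(beta, offset = 1e-6)
dm <- fit_dm(m, build_design(cohort$sheet,
                             c("age", "sex", "smoking", "mtx")), beta)
tab <- dm_table(dm, cohort$manifest, bh = TRUE)
head(tab[order(tab$p_value),
         c("probe_id", "delta_meth", "p_value", "q_value", "direction")], 5)
#>       probe_id  delta_meth      p_value      q_value        direction
#> 122 cg00000002 -0.10567607 1.583335e-17 1.254001e-14  Hypomethylation
#> 128 cg00000008 -0.04867365 1.633557e-15 5.739368e-13  Hypomethylation
#> 125 cg00000005  0.09461763 2.174003e-15 5.739368e-13 Hypermethylation
#> 121 cg00000001  0.08401769 6.888829e-14 1.363988e-11 Hypermethylation
#> 129 cg00000009  0.09079238 2.843726e-11 4.504462e-09 Hypermethylation

## 6. Stability-selected boosted classifier (reduced budget for the example)
bcfg <- boost_config(seed = 11L, n_resamples = 20, nrounds = 50,
                     n_permutations = 500)
fit <- stability_classify(t(m), cohort$sheet$response, bcfg)
c(panel_size = sum(fit$panel$in_panel),
  planted_in_panel = length(intersect(fit$panel$feature[fit$panel$in_panel],
                                      cohort$truth$informative_probe_ids)),
  test_auroc = fit$test_auroc)
#>       panel_size planted_in_panel       test_auroc
#>                8                8                1
```

All eight panel members are planted probes and the held-out AUROC is 1 —
on a small cohort with a moderate planted effect the full workflow recovers
the signal without leaking the test set (see
`tests/testthat/test-boost.R` for the leakage check).

## Tests

```r
devtools::test()        # or: testthat::test_dir("tests/testthat")
```

The suite validates each module against analytic oracles (closed-form
least squares, exact Mann–Whitney, Fisher/Brown limiting cases, brute-force
AUROC pair counting), against independent implementations (`limma`, `lm`,
`pROC`), and against the generator's ground truth, including calibration
simulations under the null. One known methodological limitation — the
anti-conservative behaviour of the panel permutation test under a
high-dimensional null — is documented in `?aggregate_pairwise` and in the
vignette, and is exercised by a deliberately strict test.
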