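#!/usr/bin/env Rscript
# Prognostic classifier: stratified 70/30 split, stability-selected gradient
# boosting against a per-resample noise probe (100 resamples over 5-fold
# stratified CV), Copeland/permutation panel aggregation, final model on the
# panel, held-out AUROC.

library(methresp)

dir.create("results", showWarnings = FALSE)
beta <- read_beta_matrix("data/cohort/beta_matrix.tsv")
sheet <- read_sample_sheet("data/cohort/sample_sheet.csv")
truth <- read_truth("data/cohort/truth.json")
m <- beta_to_m(beta, offset = 1e-6)

cfg <- boost_config(seed = 20240107L)
res <- stability_classify(t(m), sheet$response, cfg)

data.table::fwrite(res$panel, "results/panel.tsv", sep = "\t")
perf <- list(test_auroc = res$test_auroc,
             mean_cv_auroc = res$mean_cv_auroc,
             cv_auroc = res$stability$cv_auroc,
             panel_size = sum(res$panel$in_panel),
             n_train = length(res$split$train),
             n_test = length(res$split$test),
             seed = cfg$seed)
jsonlite::write_json(perf, "results/classifier_performance.json",
                     auto_unbox = TRUE, digits = NA, na = "null")
if (!is.null(res$roc)) {
  data.table::fwrite(res$roc, "results/roc_points.tsv", sep = "\t")
}

cat(sprintf("train/test: %d/%d, panel size: %d, test AUROC: %.3f, mean CV AUROC: %.3f\n",
            length(res$split$train), length(res$split$test),
            sum(res$panel$in_panel), res$test_auroc, res$mean_cv_auroc))
top15 <- res$panel$feature[1:15]
cat(sprintf("planted probes in consensus top 15: %d of %d\n",
            length(intersect(top15, truth$informative_probe_ids)),
            length(truth$informative_probe_ids)))
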