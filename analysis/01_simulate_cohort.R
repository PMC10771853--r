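#!/usr/bin/env Rscript
# Simulate the study cohort: 92 adalimumab-treated patients (49 responders /
# 43 non-responders by DAS28 criteria), EPIC-like betas over 2,000 probes with
# six-cell-type blood mixtures, 20 planted response-associated CpGs, 20
# SNP-affected tri-modal probes, and Table-2-style covariate associations.
# Writes the cohort plus ground truth under data/cohort/.

library(methresp)

seed <- 20240101L
dir.create("data", showWarnings = FALSE)

refs <- generate_reference_profiles(60, 10, seed = seed)
cfg <- generator_config(seed = seed + 1L)
cohort <- generate_cohort(cfg, refs)

paths <- write_cohort(cohort, "data/cohort", references = refs)
cat("cohort written:\n")
for (p in unlist(paths)) cat("  ", p, "\n")
cat(sprintf("samples: %d (%d responders / %d non-responders), probes: %d\n",
            nrow(cohort$sheet),
            sum(cohort$sheet$response == "responder"),
            sum(cohort$sheet$response == "non_responder"),
            nrow(cohort$beta)))
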