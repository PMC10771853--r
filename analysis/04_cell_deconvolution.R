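#!/usr/bin/env Rscript
# Reference-based cell-type deconvolution by non-negative least squares, and
# a split-plot ANOVA comparing leukocyte composition between response groups.

library(methresp)

dir.create("results", showWarnings = FALSE)
beta <- read_beta_matrix("data/cohort/beta_matrix.tsv")
sheet <- read_sample_sheet("data/cohort/sample_sheet.csv")
refs <- read_reference_profiles("data/cohort/reference_profiles.tsv")

props <- estimate_proportions(beta[rownames(refs), ], refs)
write_proportions(props, "results/cell_proportions.csv")
print(props)

truth <- read_truth("data/cohort/truth.json")
cat(sprintf("mean absolute error vs true mixing proportions: %.4f\n",
            mean(abs(props$proportions - truth$true_cell_proportions))))

cmp <- compare_proportions(props, sheet$response)
data.table::fwrite(cmp$anova, "results/cell_anova.csv", sep = ",")
data.table::fwrite(cmp$contrasts, "results/cell_contrasts.csv", sep = ",")
print(cmp$anova)
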