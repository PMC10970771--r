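#!/usr/bin/env Rscript
# Predictive modelling of dementia within the PD patients: AIC-reduced
# logistic regression over the six candidate predictors, then the
# out-of-sample ROC comparison of the seven ratio/age/UPDRS III variable
# sets on a stratified 70/30 split with bootstrap confidence intervals.

suppressMessages(library(pdmir))
seed <- 99

wells <- read_table("results/validation_wells.csv", sep = ",")
cohort <- read_table("results/validation_cohort.csv", sep = ",")
ratios <- sample_ratios(wells)
cohort <- merge(cohort, ratios[, c("sample_id", "ratio")], by = "sample_id")
cohort <- cohort[!iqr_outliers(cohort$ratio, cohort$group), ]

pd <- cohort[cohort$group != "HC", ]
pd$dementia <- dementia_label(pd$moca_total)
cat(sprintf("%d PD patients, %d with dementia (MoCA <= 21)\n",
            nrow(pd), sum(pd$dementia)))

# Full-cohort AIC reduction over the six candidate predictors.
cand <- c("age", "sex", "onset_age", "education", "updrs3", "ratio")
best <- reduce_by_aic(pd[, cand], pd$dementia)
cat(sprintf("smallest-AIC model: %s (AIC = %.2f)\n",
            paste(best$predictors, collapse = " + "), best$AIC))
aic_tab <- attr(best, "aic_table")
cat("next-best subsets:\n")
print(head(aic_tab, 5), row.names = FALSE)

# Table-4-shaped out-of-sample comparison.
tab <- model_comparison_table(pd, seed = seed, B = 2000)
fmt <- function(v, lo, hi) sprintf("%.4f (%.4f-%.4f)", v, lo, hi)
show <- data.frame(variables = tab$variables,
                   AUC = fmt(tab$auc, tab$auc_lo, tab$auc_hi),
                   sensitivity = fmt(tab$sensitivity, tab$sens_lo, tab$sens_hi),
                   specificity = fmt(tab$specificity, tab$spec_lo, tab$spec_hi),
                   accuracy = fmt(tab$accuracy, tab$acc_lo, tab$acc_hi))
print(show, row.names = FALSE)

write_table(aic_tab, "results/model_aic_table.csv", sep = ",")
write_table(tab, "results/model_comparison.csv", sep = ",")
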