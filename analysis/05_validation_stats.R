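#!/usr/bin/env Rscript
# Validation-phase statistics: Poisson quantification of every well, QC,
# the miR-203a-3p/miR-16-5p ratio per subject, the extraction-efficiency
# check, the IQR outlier rule, Kruskal-Wallis with Dunn's post hoc across
# the four groups, and the MoCA domain correlation table for PD patients.

suppressMessages(library(pdmir))

wells <- read_table("results/validation_wells.csv", sep = ",")
cohort <- read_table("results/validation_cohort.csv", sep = ",")

ratios <- sample_ratios(wells)
groups <- setNames(cohort$group, cohort$sample_id)
cat(sprintf("%d/%d samples quantified (QC pass on both assays)\n",
            nrow(ratios), nrow(cohort)))

ext <- extraction_check(wells, groups)
cat(sprintf("extraction check (miR-16-5p/UniSp6): H = %.3f, p = %.3f%s\n",
            ext$H, ext$p_value,
            if (ext$warning) "  ** efficiency differs between groups" else ""))

cohort <- merge(cohort, ratios[, c("sample_id", "ratio")], by = "sample_id")
cohort$outlier <- iqr_outliers(cohort$ratio, cohort$group)
cat(sprintf("IQR rule flags %d outlier(s): %s\n", sum(cohort$outlier),
            paste(cohort$sample_id[cohort$outlier], collapse = ", ")))
clean <- cohort[!cohort$outlier, ]

mu <- tapply(clean$ratio, clean$group, mean)
sd_ <- tapply(clean$ratio, clean$group, sd)
cat("group ratios (mean +/- SD, x 1e3):\n")
for (g in c("HC", "PDND", "PD-MCI", "PDD")) {
  cat(sprintf("  %-6s %.2f +/- %.2f\n", g, mu[[g]] * 1e3, sd_[[g]] * 1e3))
}

kw <- kruskal_wallis(clean$ratio, clean$group)
cat(sprintf("Kruskal-Wallis: H = %.2f, p = %.2g\n", kw$H, kw$p_value))
dn <- dunn_posthoc(clean$ratio, clean$group)
print(dn[, c("group1", "group2", "z", "label")], row.names = FALSE)

tab <- domain_correlation_table(clean)
cat("Spearman correlation of the ratio with MoCA (PD patients):\n")
print(transform(tab, spearman_r = round(spearman_r, 3),
                p_value = signif(p_value, 3)), row.names = FALSE)

write_table(cbind(ratios,
                  outlier = cohort$outlier[match(ratios$sample_id,
                                                 cohort$sample_id)]),
            "results/validation_ratios.csv", sep = ",")
write_table(dn, "results/validation_dunn.csv", sep = ",")
write_table(tab, "results/validation_moca_correlations.csv", sep = ",")
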