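#!/usr/bin/env Rscript
# A-priori sample size for the validation cohort: one-way fixed-effects
# ANOVA over the four study groups (HC, PDND, PD-MCI, PDD) at a large
# effect (Cohen's f = 0.5), alpha = 0.05, target power 0.8.

suppressMessages(library(pdmir))
dir.create("results", showWarnings = FALSE)

N <- min_total_n(f = 0.5, alpha = 0.05, target_power = 0.8, k = 4)
curve <- data.frame(N = 8:80)
curve$power <- vapply(curve$N, anova_power, 1, f = 0.5, alpha = 0.05, k = 4)

cat(sprintf("minimal total N for power 0.8 at f = 0.5, k = 4: %d\n", N))
cat(sprintf("achieved power at N = %d: %.4f (at N = %d: %.4f)\n",
            N, anova_power(N, 0.5, 0.05, 4),
            N - 1, anova_power(N - 1, 0.5, 0.05, 4)))

write_table(curve, "results/power_curve.tsv")
write_table(data.frame(f = 0.5, alpha = 0.05, target_power = 0.8, k = 4,
                       min_total_n = N),
            "results/power.tsv")
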