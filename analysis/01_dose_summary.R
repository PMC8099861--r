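#!/usr/bin/env Rscript
# Plan summary: PTV-to-lung volume fractions and planning-goal checks for
# the four irradiated sheep, from the bundled plan table.

library(riliquant)
dir.create("results", showWarnings = FALSE)

plans <- table1()
frac <- ptv_lung_fraction(plans)
cs <- cohort_summary(plans)
goals <- check_planning_goals(plans)

cat("PTV as % of total lung volume, per sheep:\n")
print(frac)
cat(sprintf("cohort: mean %.1f%%, range %.1f-%.1f%%\n",
            cs$mean_pct, cs$min_pct, cs$max_pct))
fails <- goals[!is.na(goals$pass) & !goals$pass, ]
cat("goal violations:\n"); print(fails, row.names = FALSE)

write.csv(data.frame(sheep_id = names(frac), ptv_lung_fraction_pct = frac),
          "results/ptv_lung_fraction.csv", row.names = FALSE)
write.csv(goals, "results/planning_goals.csv", row.names = FALSE)
cat("wrote results/ptv_lung_fraction.csv, results/planning_goals.csv\n")
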