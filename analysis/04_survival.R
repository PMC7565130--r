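#!/usr/bin/env Rscript
# Step 4 — disease-free survival by MTVcsc cutoff group.
#
# Kaplan-Meier DFS (complementary log-log 95% intervals) for the synthetic
# HER2-positive/triple-negative patients split at MTVcsc 1.75 cm^3, the
# 3-year read-out, and the log-rank comparison. The generator's hazards are
# calibrated to 90% / 72% 3-year DFS, so the estimates should bracket those
# values within sampling noise at n = 82.

suppressPackageStartupMessages(library(petcsc))
cfg <- pipeline_config(seed = 20260928L)
cohort <- read.csv("results/synthetic_cohort.csv")
her2tn <- cohort[cohort$subtype %in% c("her2_positive", "triple_negative"), ]
grp <- ifelse(her2tn$mtv_csc < cfg$cutoff, "low_mtvcsc", "high_mtvcsc")

for (g in unique(grp)) {
  sel <- grp == g
  km <- km_estimate(her2tn$dfs_months[sel], her2tn$relapse_event[sel])
  s36 <- survival_at(km, cfg$horizon)
  cat(sprintf("%s (n = %d, events = %d): 3-year DFS %.0f%% (95%% CI %.0f-%.0f%%)\n",
              g, sum(sel), sum(her2tn$relapse_event[sel]),
              s36$survival_pct, s36$ci_low_pct, s36$ci_high_pct))
  write_km_csv(km, sprintf("results/km_%s.csv", g))
}

lr <- logrank(her2tn$dfs_months, her2tn$relapse_event, grp)
cat(sprintf("log-rank: chi2 = %.2f, p = %.3f\n", lr$chi2, lr$p))
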