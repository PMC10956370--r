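#!/usr/bin/env Rscript
# Step 2: assign preliminary LI-RADS categories from major features.
#
# Applies the v2018 decision table (nonrim APHE x size bin x washout x
# capsule; threshold growth excluded) to the synthetic cohort and tabulates
# the LR-3/4/5 distribution per diagnostic group — the indeterminate LR-3/4
# stratum is what the ancillary-feature adjustment targets.

library(liradsaf)

cohort <- read_cohort_csv("results/cohort_synthetic.csv")
cats <- categorize_cohort(cohort)

dist <- table(cats$lr_initial, cats$group)
print(dist)
message(sprintf("LR-3/4 (adjustable) lesions: %d of %d (%.1f%%)",
                sum(cats$lr_initial %in% c("LR-3", "LR-4")), nrow(cats),
                100 * mean(cats$lr_initial %in% c("LR-3", "LR-4"))))

utils::write.csv(as.data.frame(dist),
                 "results/lr_distribution.csv", row.names = FALSE)
utils::write.csv(cats[, c("lesion_id", "group", "lr_initial")],
                 "results/categories_mf.csv", row.names = FALSE)
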