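#!/usr/bin/env Rscript
# Behavioural summaries: group x CIT accuracy and reaction-time
# descriptives, and Pearson correlations between CIT performance and the
# neurocognitive screening battery (NCT-A/B completion times, digit
# spans), per group and per CIT plus the CIT-total row.

library(nirscit)
library(dplyr)

seed <- 20260921L
dir.create("results", showWarnings = FALSE)
beh <- generate_behavior(seed = seed)

summ <- beh |>
  group_by(group, cit_id) |>
  summarise(acc_mean = mean(accuracy), acc_sd = sd(accuracy),
            rt_mean = mean(mean_rt_ms), rt_sd = sd(mean_rt_ms),
            .groups = "drop")
write.csv(summ, "results/behavior_summary.csv", row.names = FALSE)
print(as.data.frame(summ), digits = 3)

corr <- correlate_behavior(beh)
write.csv(corr, "results/behavior_correlations.csv", row.names = FALSE)
signs <- corr |>
  filter(test == "nct_a_s") |>
  mutate(expected = ifelse(measure == "accuracy", "negative", "positive"))
cat("\naccuracy vs NCT-A should correlate negatively, RT positively:\n")
print(as.data.frame(signs[c("group", "cit", "measure", "r", "expected")]),
      digits = 2)
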