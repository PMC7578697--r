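#!/usr/bin/env Rscript
# Simulate the study cohort: 30 chronic liver disease (CL) patients and
# 25 healthy controls (HC), each recorded over three contour
# identification task (CIT) blocks, with planted haemodynamic group
# effects at CH6/CH7/CH10 (CL higher) and CH13/CH14/CH16 (CL lower),
# plus the behavioural tables. Writes labels, behaviour and the CIT
# design tables under results/.

library(nirscit)

seed <- 20260921L
dir.create("results", showWarnings = FALSE)

coh <- generate_cohort(seed = seed)
write.csv(coh$labels, "results/labels.csv", row.names = FALSE)

beh <- generate_behavior(seed = seed)
write.csv(beh, "results/behavior.csv", row.names = FALSE)

pool <- build_item_pool()
write.csv(pool, "results/item_pool.csv", row.names = FALSE)
blocks <- do.call(rbind, lapply(1:3, function(i) {
  b <- build_cit_block(paste0("CIT", i), pool, 18, seed = seed + i)
  cbind(cit = b$cit_id, b$trials)
}))
write.csv(blocks, "results/cit_blocks.csv", row.names = FALSE)

cat("cohort:", nrow(coh$labels), "subjects;",
    nrow(beh), "behaviour rows;", nrow(pool), "stimulus items\n")
cat("item duration:", pool$duration_ms[1], "ms;",
    "18 items per block x 3 blocks\n")
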