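#!/usr/bin/env Rscript
# Weight-sign matrix of the best bilateral subsets: for each of the top
# 50 subsets the SVM is refit on the full CIT1+CIT2 table and each
# member channel's signed weight recorded (positive = higher HbO2 in
# CL). Channels planted positive (CH6/CH7/CH10) should show red/positive
# weights and the planted-negative ones (CH13/CH14/CH16) blue/negative.

library(nirscit)

feats <- read.csv("results/features_cit1_cit2.csv")
bi <- read.csv("results/search_bilateral.csv")
attr(bi, "grouping") <- "bilateral"

wm <- weight_sign_matrix(feats, bi, m = 50)
write.csv(cbind(subset = rownames(wm), as.data.frame(wm)),
          "results/weight_sign_matrix.csv", row.names = FALSE)

sign_summary <- apply(wm, 2, function(col) {
  col <- col[!is.na(col)]
  if (length(col) == 0) return(NA_real_)
  mean(sign(col))
})
cat("mean weight sign per channel over the top 50 subsets:\n")
print(round(sign_summary, 2))
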