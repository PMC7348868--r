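#!/usr/bin/env Rscript
# Step 2: preprocess and featurize every session.
#
# Each session is synthesised from its manifest row, preprocessed (IQR
# outlier interpolation by cubic smoothing spline, 0.99 peak
# normalization, edge-silence trimming) and summarised into the 108
# session features (36 frame features x mean/median/SD).

library(pseudovoice)

for (cohort in c("main", "transfer")) {
  manifest <- read_manifest(sprintf("results/manifest_%s.csv", cohort))
  co <- list(manifest = manifest)
  class(co) <- "speech_cohort"
  ft <- cohort_features(co, verbose = TRUE)
  utils::write.csv(ft, sprintf("results/features_%s.csv", cohort),
                   row.names = FALSE)
  message(cohort, ": ", nrow(ft), " sessions x ", ncol(ft) - 2,
          " features written")
}
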