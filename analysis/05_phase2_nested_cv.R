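#!/usr/bin/env Rscript
# Step 5 (phase 2): supervised screening by nested 10-fold CV.
#
# Linear-kernel SVM with cost tuned by inner-CV grid search; run once
# without feature selection and once with the LASSO-vote removal (a
# feature is dropped from an outer fold when its |coefficient| < 0.01 in
# all 10 inner folds at the near-threshold penalty).

library(pseudovoice)

ft <- utils::read.csv("results/features_main.csv")
y <- labels_from_group(ft$group)

rows <- list()
for (with_lasso in c(FALSE, TRUE)) {
  cv <- nested_cv(ft, y, kernel = "linear", with_lasso = with_lasso,
                  seed = 11)
  tag <- if (with_lasso) "with_lasso" else "no_lasso"
  s <- merge(cv$summary$train, cv$summary$test, by = "metric",
             suffixes = c("_train", "_test"), sort = FALSE)
  s$selection <- tag
  rows[[tag]] <- s
  if (with_lasso) {
    keep <- phase2_retained_features(cv)
    jsonlite::write_json(
      list(retained_any_fold = names(keep)[keep],
           completely_rejected = names(keep)[!keep],
           per_fold_retained_counts = rowSums(cv$retained)),
      "results/phase2_selection.json", auto_unbox = TRUE, pretty = TRUE)
    message(sum(!keep), " of ", length(keep),
            " features completely rejected by the LASSO vote")
  }
  message(sprintf("phase 2 (%s): test ACC %.1f +/- %.1f %%", tag,
                  s$mean_pct_test[s$metric == "acc"],
                  s$sd_pct_test[s$metric == "acc"]))
}
utils::write.csv(do.call(rbind, rows), "results/phase2_linear.csv",
                 row.names = FALSE)
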