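#!/usr/bin/env Rscript
# Step 6 (phase 3): transfer evaluation on the non-age-matched cohort.
#
# A final linear SVM is trained on the full main cohort using the features
# that survived phase 2 in at least one outer fold, then evaluated once --
# no refitting, standardization frozen -- on the young-depression /
# old-dementia transfer cohort. Feature contributions (|linear SVM
# coefficients|) of the final model are also written.

library(pseudovoice)

ft <- utils::read.csv("results/features_main.csv")
y <- labels_from_group(ft$group)
sel <- jsonlite::read_json("results/phase2_selection.json",
                           simplifyVector = TRUE)
keep <- sel$retained_any_fold

x <- as.matrix(ft[, setdiff(names(ft), c("session_id", "group"))])
cv_cost <- grid_search(x[, keep], y, kernel = "linear",
                       inner_folds = local({
                         set.seed(11); stratified_folds(y, 10)
                       }))
model <- train_svm(x[, keep], y, kernel = "linear", cost = cv_cost$cost)

tf <- utils::read.csv("results/features_transfer.csv")
yt <- labels_from_group(tf$group)
ev <- transfer_evaluate(model, tf, yt)
res <- data.frame(metric = names(ev$metrics),
                  value_pct = round(100 * as.numeric(ev$metrics), 1))
utils::write.csv(res, "results/phase3_transfer.csv", row.names = FALSE)
message(sprintf(
  "phase 3 transfer (n=%d, %d/%d): ACC %.1f%%, kappa %.1f%%, MCC %.1f%%",
  length(yt), sum(yt == 1), sum(yt == 0),
  res$value_pct[res$metric == "acc"],
  res$value_pct[res$metric == "kappa"],
  res$value_pct[res$metric == "mcc"]))

fc <- feature_contributions(model)
utils::write.csv(fc, "results/feature_contributions.csv", row.names = FALSE)
message("top contributing features: ",
        paste(head(fc$feature, 5), collapse = ", "))
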