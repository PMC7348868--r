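#!/usr/bin/env Rscript
# Step 1: simulate the study cohorts.
#
# Two synthetic cohorts stand in for the clinical recordings (which are not
# public): an age-matched analysis cohort (depression vs dementia, ages
# 57-84) and a non-age-matched transfer cohort (young depression <= 56,
# old dementia >= 85). Session audio is synthesised deterministically on
# demand from the manifest (source-filter model), so only the manifests
# are persisted here. Desk-scale sizes: 40 + 40 main sessions and 35 + 10
# transfer sessions of 10 s each.

library(pseudovoice)

dir.create("results", showWarnings = FALSE)

main_spec <- cohort_spec(40, 40, session_seconds = 10, class_separation = 3,
                         seed = 2024)
main <- generate_cohort(main_spec)
write_manifest(main, "results/manifest_main.csv")

transfer_spec <- cohort_spec(
  35, 10, session_seconds = 10, class_separation = 3,
  age_params = list(
    depression = list(mean = 42.5, sd = 10.4, min = 20, max = 56),
    dementia = list(mean = 88.5, sd = 1.9, min = 85, max = 95)),
  female_pct = c(depression = 0.415, dementia = 0.714),
  seed = 2025)
transfer <- generate_cohort(transfer_spec)
write_manifest(transfer, "results/manifest_transfer.csv")

part <- filter_cohort(main$manifest, min_duration_s = 0)
message("main cohort: ", nrow(main$manifest), " sessions (",
        part$counts["age_matched"], " age-matched, ",
        part$counts["excluded"], " excluded)")
tpart <- filter_cohort(transfer$manifest, min_duration_s = 0)
message("transfer cohort: ", nrow(transfer$manifest), " sessions (",
        tpart$counts["transfer_test"], " in the transfer band)")
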