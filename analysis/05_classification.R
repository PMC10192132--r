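#!/usr/bin/env Rscript
# Stage 5 — expert/novice classification.
#
# Samples are subject-presentation pairs with one HFD feature per channel.
# Hyperparameters (kNN neighbours, linear-SVM C, tree depth, AdaBoost
# rounds) are tuned by ten-fold CV under the pooled subject-presentation
# split, then frozen for the subject-specific and presentation-specific
# splits. The pooled split can exploit subject identity (samples of one
# subject on both sides of a fold), so its accuracy upper-bounds the
# subject-level splits — the central methodological caveat this analysis
# demonstrates. Finally the full montage is compared against the standard
# low-density subset, which here excludes every effect channel.

source("analysis/00_config.R")

features <- data.table::fread(file.path(results_dir, "hfd_features.csv"),
                              data.table = FALSE)
class(features) <- c("hfd_table", "data.frame")

samples <- assemble_samples(features)
message(sprintf("sample table: %d subject-presentation pairs x %d features",
                nrow(samples), ncol(samples) - 3))

report <- run_grid(samples,
                   c("subject_presentation", "subject_specific",
                     "presentation_specific"),
                   default_grid(), seeds = c(0, 1, 2), n_folds = 10)
best <- best_per_scheme(report)
message("best mean validation accuracy per scheme:")
print(best, row.names = FALSE)
gap <- best$mean_accuracy[best$scheme == "subject_presentation"][1] -
  best$mean_accuracy[best$scheme == "subject_specific"][1]
message(sprintf("identity-leakage gap (case 1 minus case 2): %+.3f", gap))

cmp <- compare_channel_sets(features, analysis_montage,
                            grid = default_grid(), seeds = c(0, 1, 2),
                            n_folds = 10)
acc_sets <- tapply(cmp$accuracy, cmp$channel_set, mean)
message(sprintf(
  "montage comparison: full %d-channel %.3f vs standard subset %.3f",
  length(eeg_channels(analysis_montage)), acc_sets[["full"]],
  acc_sets[["standard32"]]))

save_table(report, "accuracy_report.csv")
save_table(best, "best_per_scheme.csv")
save_table(cmp, "channel_set_comparison.csv")
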