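#!/usr/bin/env Rscript
# Stage 4 — channel-level group statistics.
#
# Expert-minus-novice HFD contrast per channel (double mean: over
# presentations within subject, then over subjects), one-sided Welch
# t-tests on subject means, top-10 ranking, the eyes-open resting-state
# control (no effect expected), the algebraic-vs-geometric style contrast
# within experts (no effect expected), and the topographic value export.

source("analysis/00_config.R")

features <- data.table::fread(file.path(results_dir, "hfd_features.csv"),
                              data.table = FALSE)
class(features) <- c("hfd_table", "data.frame")

contrasts <- channel_tests(features)        # expert < novice, one-sided
top10 <- top_channels(contrasts, 10)
message("top 10 channels by |expert - novice| mean HFD:")
print(top10[, c("channel", "delta", "p_value", "significant")],
      row.names = FALSE)
message(sprintf("%d of %d channels significant at p < 0.05 (effect sits on %s)",
                sum(contrasts$significant), nrow(contrasts),
                paste(analysis_config$effect_channels, collapse = ", ")))

rest <- channel_tests(features, condition = "rest")
message(sprintf("resting-state control: %d of %d channels significant",
                sum(rest$significant), nrow(rest)))

style <- style_contrast(features, group = "expert")
message(sprintf("algebraic vs geometric (experts): %d channels significant",
                sum(style$significant)))

save_table(contrasts, "channel_contrasts.csv")
save_table(top10, "top_channels.csv")
save_table(rest, "rest_contrasts.csv")
save_table(style, "style_contrast_expert.csv")
save_table(export_topography(contrasts, analysis_montage), "topography.csv")
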