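# Small montages and cohorts for fast tests. The reduced montage keeps the
# structure of the default one (a 10/20-style subset, high-density filler
# sites outside it, auxiliary leads) at a fraction of the channel count.

small_montage <- function(n_std = 8, n_filler = 8) {
  montage_spec(
    channel_names = c(sprintf("S%d", seq_len(n_std)),
                      sprintf("X%d", seq_len(n_filler)), "VEOGL", "HEART"),
    auxiliary_names = c("VEOGL", "HEART"),
    standard32_names = sprintf("S%d", seq_len(n_std)))
}

# Effect channels sit on filler sites (outside the standard subset), as in
# the default configuration.
small_config <- function(seed = 1, n_subjects = 6, n_pairs = 2,
                         duration = c(6, 8), sampling_rate = 128,
                         effect_delta_fd = 0.15, subject_sd = 0.05,
                         effect_channels = c("X1", "X2"), ...) {
  cohort_config(n_experts = n_subjects, n_novices = n_subjects,
                n_presentation_pairs = n_pairs, duration_range = duration,
                rest_duration = duration[1], sampling_rate = sampling_rate,
                effect_channels = effect_channels,
                effect_delta_fd = effect_delta_fd, subject_sd = subject_sd,
                seed = seed, ...)
}

small_cohort <- function(seed = 1, ...) {
  generate_cohort(small_config(seed = seed, ...), small_montage())
}

small_features <- function(seed = 1, k_max = 8, conditions = "task", ...) {
  extract_features(small_cohort(seed = seed, ...), hfd_params(k_max),
                   conditions = conditions)
}

# Hand-built long-format feature table (for contract tests that need exact
# values rather than simulated signals).
manual_hfd_table <- function(subject_id, group, presentation_id, channel,
                             hfd, condition = "task") {
  df <- data.frame(subject_id = subject_id, group = group,
                   condition = condition, presentation_id = presentation_id,
                   channel = channel, window = 0L, hfd = hfd,
                   stringsAsFactors = FALSE)
  attr(df, "params") <- hfd_params(8)
  class(df) <- c("hfd_table", "data.frame")
  df
}
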