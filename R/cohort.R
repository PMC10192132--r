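#' Configuration of a synthetic EEG expertise cohort
#'
#' Parameters of the simulated study: two groups of subjects (math experts
#' and novices) each watching `2 * n_presentation_pairs` task presentations
#' (matched algebraic/geometric pairs, labelled `1A`,`1G`,...) plus one
#' eyes-open resting recording. Every non-auxiliary channel carries a
#' power-law signal at fractal dimension `baseline_fd` plus a subject-level
#' random offset; during task, the channels in `effect_channels` of the
#' group named by `effect_group` are shifted by `effect_delta_fd`. No group
#' effect exists at rest, by construction.
#'
#' @param n_experts,n_novices subjects per group (default 22 each).
#' @param n_presentation_pairs number of matched A/G presentation pairs
#'   (default 8, i.e. 16 task presentations per subject).
#' @param duration_range presentation duration range in seconds; each pair's
#'   duration is drawn uniformly from it and is identical across subjects
#'   and within the A/G pair (default `c(13, 68)`).
#' @param rest_duration duration of the resting recording in seconds.
#' @param sampling_rate sampling rate in Hz. Default 256 (desk scale); the
#'   acquisition-grade 2048 Hz is supported as a configuration value.
#' @param baseline_fd target fractal dimension of unaffected channels,
#'   strictly in (1, 2); default 1.6.
#' @param effect_channels channel labels carrying the group effect during
#'   task. Default `E1`..`E4`: high-density sites outside the 10/20 subset.
#' @param effect_delta_fd signed FD offset applied to `effect_group` on
#'   `effect_channels` during task (default +0.15).
#' @param effect_group which group receives the offset; default `"novice"`
#'   (novices show higher task signal complexity on the effect channels).
#' @param subject_sd standard deviation of the per-subject FD offset shared
#'   across all of that subject's channels and recordings (default 0.05).
#' @param noise_sd relative amplitude of the additive white measurement
#'   noise (default 0.05).
#' @param band_limit_hz low-pass synthesis cut-off in Hz (default 40): the
#'   generated brain signals carry negligible power above it, standing in
#'   for band-limited acquisition/preprocessing. Use `NULL` for full band.
#' @param amplitude_uv overall signal scale in microvolts (default 10).
#' @param seed master integer seed; every recording and subject offset is a
#'   deterministic function of it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_experts = 22, n_novices = 22,
                          n_presentation_pairs = 8,
                          duration_range = c(13, 68),
                          rest_duration = 60,
                          sampling_rate = 256,
                          baseline_fd = 1.6,
                          effect_channels = c("E1", "E2", "E3", "E4"),
                          effect_delta_fd = 0.15,
                          effect_group = c("novice", "expert"),
                          subject_sd = 0.05,
                          noise_sd = 0.05,
                          band_limit_hz = 40,
                          amplitude_uv = 10,
                          seed = 1) {
  effect_group <- match.arg(effect_group)
  if (baseline_fd <= 1 || baseline_fd >= 2)
    stop_hfd("baseline_fd must lie strictly in (1, 2)")
  if (baseline_fd + effect_delta_fd <= 1 || baseline_fd + effect_delta_fd >= 2)
    stop_hfd("baseline_fd + effect_delta_fd must lie strictly in (1, 2)")
  if (length(duration_range) != 2 || any(duration_range <= 0) ||
      duration_range[1] > duration_range[2])
    stop_hfd("duration_range must be two positive, ordered values")
  if (sampling_rate <= 0) stop_hfd("sampling_rate must be positive")
  if (rest_duration <= 0) stop_hfd("rest_duration must be positive")
  if (n_experts < 1 || n_novices < 1 || n_presentation_pairs < 1)
    stop_hfd("cohort counts must be at least 1")
  if (subject_sd < 0 || noise_sd < 0)
    stop_hfd("subject_sd and noise_sd must be non-negative")
  structure(
    list(n_experts = n_experts, n_novices = n_novices,
         n_presentation_pairs = n_presentation_pairs,
         duration_range = duration_range, rest_duration = rest_duration,
         sampling_rate = sampling_rate, baseline_fd = baseline_fd,
         effect_channels = as.character(effect_channels),
         effect_delta_fd = effect_delta_fd, effect_group = effect_group,
         subject_sd = subject_sd, noise_sd = noise_sd,
         band_limit_hz = band_limit_hz, amplitude_uv = amplitude_uv,
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<cohort_config> %d experts + %d novices, %d A/G pairs (%d task ",
    "presentations), fs = %g Hz\n  baseline FD %.2f, effect %+.2f on {%s} ",
    "for %ss (task only), subject sd %.3f, noise sd %.3f, seed %d\n"),
    x$n_experts, x$n_novices, x$n_presentation_pairs,
    2 * x$n_presentation_pairs, x$sampling_rate, x$baseline_fd,
    x$effect_delta_fd, paste(x$effect_channels, collapse = ","),
    x$effect_group, x$subject_sd, x$noise_sd, x$seed))
  invisible(x)
}

# FD targets are kept strictly inside (1, 2): the power-law exponent is
# undefined at the endpoints.
clamp_fd <- function(fd) pmin(pmax(fd, 1.01), 1.99)

subject_roster <- function(config) {
  ids <- c(sprintf("expert%02d", seq_len(config$n_experts)),
           sprintf("novice%02d", seq_len(config$n_novices)))
  grp <- rep(c("expert", "novice"), c(config$n_experts, config$n_novices))
  set.seed(derive_seed(config$seed, "subject-offsets"))
  data.frame(subject_id = ids, group = grp,
             fd_offset = rnorm(length(ids), 0, config$subject_sd),
             stringsAsFactors = FALSE)
}

presentation_table <- function(config) {
  set.seed(derive_seed(config$seed, "presentation-durations"))
  pair_dur <- runif(config$n_presentation_pairs,
                    config$duration_range[1], config$duration_range[2])
  pairs <- seq_len(config$n_presentation_pairs)
  data.frame(
    presentation_id = as.vector(rbind(sprintf("%dA", pairs), sprintf("%dG", pairs))),
    style = rep(c("A", "G"), config$n_presentation_pairs),
    duration = rep(pair_dur, each = 2),   # matched within an A/G pair
    stringsAsFactors = FALSE)
}

#' Build the manifest of a synthetic cohort
#'
#' The manifest is the roster: subjects with group labels (and their hidden
#' subject-level FD offsets), presentations with styles and durations
#' (identical across subjects, matched within each A/G pair), and the index
#' of all recordings with their deterministic per-recording seeds.
#'
#' @param config a [cohort_config()].
#' @param montage a [montage_spec()].
#' @return A list of class `cohort_manifest` with elements `subjects`,
#'   `presentations` and `recordings`.
#' @export
build_manifest <- function(config, montage = default_montage()) {
  missing_ch <- setdiff(config$effect_channels, eeg_channels(montage))
  if (length(missing_ch))
    stop_hfd("configuration error: effect_channels not in the montage's ",
             "EEG channels: ", paste(missing_ch, collapse = ", "))
  subjects <- subject_roster(config)
  pres <- presentation_table(config)
  task <- expand.grid(subject_id = subjects$subject_id,
                      presentation_id = pres$presentation_id,
                      stringsAsFactors = FALSE)
  task$condition <- "task"
  task$duration <- pres$duration[match(task$presentation_id, pres$presentation_id)]
  rest <- data.frame(subject_id = subjects$subject_id,
                     presentation_id = NA_character_,
                     condition = "rest", duration = config$rest_duration,
                     stringsAsFactors = FALSE)
  rec <- rbind(task, rest)
  rec$group <- subjects$group[match(rec$subject_id, subjects$subject_id)]
  rec$seed <- mapply(function(s, c, p) derive_seed(config$seed, "recording",
                                                   s, c, p %||% "rest"),
                     rec$subject_id, rec$condition,
                     ifelse(is.na(rec$presentation_id), "rest",
                            rec$presentation_id))
  rec <- rec[, c("subject_id", "group", "condition", "presentation_id",
                 "duration", "seed")]
  rownames(rec) <- NULL
  structure(list(subjects = subjects, presentations = pres,
                 recordings = rec),
            class = "cohort_manifest")
}

#' Generate one synthetic EEG recording
#'
#' Every non-auxiliary channel carries a power-law fractal signal at
#' `baseline_fd + subject_offset`; if `condition == "task"` and the subject
#' belongs to the configured effect group, channels in
#' `config$effect_channels` are additionally shifted by
#' `config$effect_delta_fd`. Auxiliary channels carry unrelated white
#' noise. White measurement noise of relative amplitude `config$noise_sd`
#' is mixed into every brain channel.
#'
#' @param subject_id,group,condition,presentation_id recording identity;
#'   `condition` is `"task"` or `"rest"`, `presentation_id` is `NA` at rest.
#' @param duration recording duration in seconds.
#' @param config a [cohort_config()].
#' @param montage a [montage_spec()].
#' @param seed integer seed for this recording.
#' @param subject_offset subject-level FD offset (defaults to 0; cohort
#'   generation passes the roster value).
#' @return An object of class `eeg_recording`: list with the
#'   `channels x samples` signal matrix (microvolts), sampling rate,
#'   montage and identity fields.
#' @export
generate_recording <- function(subject_id, group, condition,
                               presentation_id, duration, config,
                               montage = default_montage(), seed,
                               subject_offset = 0) {
  condition <- match.arg(condition, c("task", "rest"))
  group <- match.arg(group, c("expert", "novice"))
  eeg <- eeg_channels(montage)
  missing_ch <- setdiff(config$effect_channels, eeg)
  if (length(missing_ch))
    stop_hfd("configuration error: effect_channels not in the montage's ",
             "EEG channels: ", paste(missing_ch, collapse = ", "))
  n <- round(duration * config$sampling_rate)
  ch <- montage$channel_names
  fds <- rep(NA_real_, length(ch))             # NA -> auxiliary white noise
  is_eeg <- ch %in% eeg
  fds[is_eeg] <- clamp_fd(config$baseline_fd + subject_offset)
  if (condition == "task" && group == config$effect_group)
    fds[ch %in% config$effect_channels] <-
      clamp_fd(config$baseline_fd + subject_offset + config$effect_delta_fd)
  set.seed(as.integer(seed))
  sig <- synth_recording_matrix(n, fds, config$sampling_rate,
                                config$noise_sd, config$band_limit_hz,
                                config$amplitude_uv)
  structure(
    list(subject_id = subject_id, group = group, condition = condition,
         presentation_id = presentation_id,
         signal = t(sig),                       # channels x samples
         sampling_rate = config$sampling_rate, montage = montage),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s/%s/%s: %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$condition,
              if (is.na(x$presentation_id)) "-" else x$presentation_id,
              nrow(x$signal), ncol(x$signal), x$sampling_rate))
  invisible(x)
}

#' Generate a synthetic EEG cohort
#'
#' Builds the cohort manifest and either keeps the cohort lazy (recordings
#' are regenerated on demand from their deterministic seeds; nothing is
#' written) or materialises every recording under `dir` as columnar CSV
#' files with JSON sidecars plus a `manifest.json`.
#'
#' @param config a [cohort_config()].
#' @param montage a [montage_spec()].
#' @param dir optional output directory; `NULL` (default) keeps the cohort
#'   in lazy, on-demand form.
#' @param overwrite refuse to overwrite an existing manifest unless `TRUE`.
#' @return An object of class `eeg_cohort`: `manifest`, `config`,
#'   `montage`, `dir`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            montage = default_montage(), dir = NULL,
                            overwrite = FALSE) {
  manifest <- build_manifest(config, montage)
  cohort <- structure(list(manifest = manifest, config = config,
                           montage = montage, dir = dir),
                      class = "eeg_cohort")
  if (!is.null(dir)) {
    mpath <- file.path(dir, "manifest.json")
    if (file.exists(mpath) && !overwrite)
      stop_hfd("refusing to overwrite existing cohort manifest at ", mpath,
               " (set overwrite = TRUE)")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    rec <- manifest$recordings
    for (i in seq_len(nrow(rec))) {
      r <- generate_recording(rec$subject_id[i], rec$group[i],
                              rec$condition[i], rec$presentation_id[i],
                              rec$duration[i], config, montage, rec$seed[i],
                              subject_offset = subject_fd_offset(
                                manifest, rec$subject_id[i]))
      write_recording(r, file.path(dir, recording_stem(rec[i, ])))
    }
    write_manifest(cohort, mpath)
  }
  cohort
}

subject_fd_offset <- function(manifest, subject_id) {
  manifest$subjects$fd_offset[match(subject_id, manifest$subjects$subject_id)]
}

recording_stem <- function(rec_row) {
  sprintf("%s_%s", rec_row$subject_id,
          if (is.na(rec_row$presentation_id)) "rest" else rec_row$presentation_id)
}

#' @export
print.eeg_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<eeg_cohort> %d subjects (%d expert / %d novice), %d recordings (%s)\n",
              nrow(m$subjects), sum(m$subjects$group == "expert"),
              sum(m$subjects$group == "novice"), nrow(m$recordings),
              if (is.null(x$dir)) "lazy" else x$dir))
  invisible(x)
}

#' Recording index of a cohort
#'
#' @param cohort an [generate_cohort()] result.
#' @return The recordings data frame of the manifest (subject, group,
#'   condition, presentation, duration, seed).
#' @export
cohort_recordings <- function(cohort) cohort$manifest$recordings

#' Fetch one recording from a cohort
#'
#' Lazy cohorts regenerate the recording deterministically from its seed;
#' materialised cohorts read it back from disk.
#'
#' @param cohort an `eeg_cohort`.
#' @param subject_id subject identifier.
#' @param condition `"task"` or `"rest"`.
#' @param presentation_id presentation label (required for task).
#' @return An `eeg_recording`.
#' @export
get_recording <- function(cohort, subject_id, condition = "task",
                          presentation_id = NULL) {
  rec <- cohort$manifest$recordings
  hit <- rec$subject_id == subject_id & rec$condition == condition &
    (if (condition == "rest") TRUE else rec$presentation_id == presentation_id)
  if (!any(hit))
    stop_hfd("no such recording: subject ", subject_id, ", condition ",
             condition,
             if (!is.null(presentation_id)) paste0(", presentation ",
                                                   presentation_id))
  row <- rec[which(hit)[1], ]
  if (!is.null(cohort$dir)) {
    path <- file.path(cohort$dir, recording_stem(row))
    if (!file.exists(paste0(path, ".csv")))
      stop_hfd("missing recording file for subject ", row$subject_id,
               ", presentation ",
               if (is.na(row$presentation_id)) "rest" else row$presentation_id,
               ": ", path, ".csv")
    return(read_recording(path))
  }
  generate_recording(row$subject_id, row$group, row$condition,
                     row$presentation_id, row$duration, cohort$config,
                     cohort$montage, row$seed,
                     subject_offset = subject_fd_offset(cohort$manifest,
                                                        row$subject_id))
}
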