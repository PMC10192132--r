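# On-disk recording format: <stem>.csv holds the signal with one column per
# channel (header row = channel labels, samples as rows, full double
# precision); <stem>.json holds the metadata (identity, sampling rate,
# montage, n_samples). The pair round-trips losslessly.

#' Write a recording to disk
#'
#' @param recording an `eeg_recording`.
#' @param path file stem (without extension); writes `<path>.csv` and
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  sig <- t(recording$signal)                     # samples x channels
  colnames(sig) <- recording$montage$channel_names
  data.table::fwrite(data.table::as.data.table(sig),
                     paste0(path, ".csv"))
  meta <- list(subject_id = recording$subject_id, group = recording$group,
               condition = recording$condition,
               presentation_id = recording$presentation_id,
               sampling_rate = recording$sampling_rate,
               n_samples = ncol(recording$signal),
               channel_names = recording$montage$channel_names,
               auxiliary_names = recording$montage$auxiliary_names,
               standard32_names = recording$montage$standard32_names)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording from disk
#'
#' Validates the stored signal against the sidecar metadata and raises a
#' parse error naming the offending field on mismatch (e.g. a truncated
#' file is reported, never silently accepted).
#'
#' @param path file stem written by [write_recording()].
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path) {
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  if (!file.exists(csv)) stop_hfd("recording signal file not found: ", csv)
  if (!file.exists(js)) stop_hfd("recording metadata file not found: ", js)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  for (field in c("subject_id", "group", "condition", "sampling_rate",
                  "n_samples", "channel_names"))
    if (is.null(meta[[field]]))
      stop_hfd("parse error in ", js, ": missing field '", field, "'")
  sig <- as.matrix(data.table::fread(csv))
  if (!identical(colnames(sig), as.character(meta$channel_names)))
    stop_hfd("parse error in ", csv, ": field 'channel_names' does not ",
             "match the CSV header")
  if (nrow(sig) != meta$n_samples)
    stop_hfd("parse error in ", csv, ": field 'n_samples' is ",
             meta$n_samples, " but the file holds ", nrow(sig),
             " rows (truncated file?)")
  if (!all(is.finite(sig)))
    stop_hfd("parse error in ", csv, ": field 'signal' contains ",
             "non-finite values")
  montage <- montage_spec(meta$channel_names,
                          meta$auxiliary_names %||% character(),
                          meta$standard32_names %||% character())
  structure(
    list(subject_id = meta$subject_id, group = meta$group,
         condition = meta$condition,
         presentation_id = if (is.null(meta$presentation_id))
           NA_character_ else meta$presentation_id,
         signal = t(sig), sampling_rate = as.numeric(meta$sampling_rate),
         montage = montage),
    class = "eeg_recording")
}

write_manifest <- function(cohort, path) {
  m <- cohort$manifest
  jsonlite::write_json(
    list(config = unclass(cohort$config),
         subjects = m$subjects, presentations = m$presentations,
         recordings = m$recordings,
         files = sapply(seq_len(nrow(m$recordings)), function(i)
           paste0(recording_stem(m$recordings[i, ]), ".csv"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a materialised cohort from disk
#'
#' @param dir directory written by [generate_cohort()] with `dir` set.
#' @return An `eeg_cohort` whose recordings are read from disk on demand.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop_hfd("no manifest.json under ", dir)
  m <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  cfg <- m$config
  config <- cohort_config(
    n_experts = cfg$n_experts, n_novices = cfg$n_novices,
    n_presentation_pairs = cfg$n_presentation_pairs,
    duration_range = cfg$duration_range, rest_duration = cfg$rest_duration,
    sampling_rate = cfg$sampling_rate, baseline_fd = cfg$baseline_fd,
    effect_channels = cfg$effect_channels,
    effect_delta_fd = cfg$effect_delta_fd, effect_group = cfg$effect_group,
    subject_sd = cfg$subject_sd, noise_sd = cfg$noise_sd,
    band_limit_hz = cfg$band_limit_hz, amplitude_uv = cfg$amplitude_uv,
    seed = cfg$seed)
  first <- read_recording(file.path(dir, sub("\\.csv$", "", m$files[1])))
  manifest <- structure(list(subjects = as.data.frame(m$subjects),
                             presentations = as.data.frame(m$presentations),
                             recordings = as.data.frame(m$recordings)),
                        class = "cohort_manifest")
  structure(list(manifest = manifest, config = config,
                 montage = first$montage, dir = dir),
            class = "eeg_cohort")
}
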