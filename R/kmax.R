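# k_max tuning.
#
# The HFD log-log fit grows with k_max and eventually plateaus; an
# uninformative k_max washes out the contrast between channels. The tuning
# procedure sweeps a candidate grid, computing (a) the grand mean HFD over
# subjects, presentations and channels, and (b) the grand mean of the
# per-recording max-minus-min HFD across channels ("spread": the minimum is
# the baseline fractal dimension and is subtracted from the maximum, the
# complexity of the most responsive channels). The selected k_max maximizes
# the spread, preferring — within tolerance — a candidate where the mean
# HFD has begun to plateau.

#' Per-recording channel spread of HFD values
#'
#' For every (subject, condition, presentation) cell: the maximum HFD
#' across channels minus the minimum across channels.
#'
#' @param features an `hfd_table` from [extract_features()].
#' @return Data frame with `subject_id`, `condition`, `presentation_id`
#'   and `spread`.
#' @export
channel_spread <- function(features) {
  if (length(unique(features$channel)) < 2)
    stop_hfd("channel spread needs at least 2 channels per recording")
  key <- interaction(features$subject_id, features$condition,
                     ifelse(is.na(features$presentation_id), "rest",
                            features$presentation_id), drop = TRUE)
  sp <- tapply(features$hfd, key, function(v) max(v) - min(v))
  first <- !duplicated(key)
  out <- data.frame(subject_id = features$subject_id[first],
                    condition = features$condition[first],
                    presentation_id = features$presentation_id[first],
                    spread = as.numeric(sp[as.character(key[first])]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Slopes of the log-log fit for every candidate prefix of a length table.
# L: matrix (k_max_big x n_channels) of curve lengths; candidates index
# prefixes. Vectorized over channels.
slopes_for_candidates <- function(L, candidates) {
  lk <- log(1 / seq_len(nrow(L)))
  logL <- log(L)
  vapply(candidates, function(km) {
    x <- lk[1:km]; xc <- x - mean(x)
    y <- logL[1:km, , drop = FALSE]
    yc <- sweep(y, 2, colMeans(y))
    colSums(yc * xc) / sum(xc^2)
  }, numeric(ncol(L)))
}

#' Sweep HFD over a grid of k_max candidates
#'
#' Computes, for each candidate, the grand mean HFD across all recordings
#' and channels and the grand mean per-recording channel spread. Curve
#' lengths are computed once per channel up to the largest feasible
#' candidate and reused for every prefix, so the sweep costs little more
#' than a single extraction at the largest k_max. Candidates needing more
#' samples than a recording provides (`2 * k_max > n_samples`) are skipped
#' for that recording, with a warning.
#'
#' @param cohort an `eeg_cohort`.
#' @param candidates strictly increasing integer candidates, all at least
#'   2; default `c(2, 5, 20, 100, 150, 200, 400)`.
#' @param conditions conditions to include (default task only).
#' @return Data frame of class `kmax_sweep`: `k_max`, `mean_hfd`,
#'   `mean_spread`, `n_recordings`.
#' @export
sweep_kmax <- function(cohort, candidates = c(2, 5, 20, 100, 150, 200, 400),
                       conditions = "task") {
  candidates <- sort(unique(as.integer(candidates)))
  if (any(candidates < 2)) stop_hfd("all k_max candidates must be >= 2")
  rec_index <- cohort$manifest$recordings
  rec_index <- rec_index[rec_index$condition %in% conditions, , drop = FALSE]
  eeg <- eeg_channels(cohort$montage)
  nc <- length(candidates)
  hfd_sum <- numeric(nc); spread_sum <- numeric(nc); n_used <- integer(nc)
  skipped <- FALSE
  for (i in seq_len(nrow(rec_index))) {
    row <- rec_index[i, ]
    r <- get_recording(cohort, row$subject_id, row$condition,
                       row$presentation_id)
    n <- ncol(r$signal)
    feasible <- which(2 * candidates <= n)
    if (length(feasible) < length(candidates)) skipped <- TRUE
    if (!length(feasible)) next
    kbig <- max(candidates[feasible])
    sig <- r$signal[match(eeg, r$montage$channel_names), , drop = FALSE]
    L <- vapply(seq_len(nrow(sig)),
                function(ch) cpp_higuchi_lengths(sig[ch, ], kbig),
                numeric(kbig))                    # kbig x n_channels
    slopes <- slopes_for_candidates(L, candidates[feasible])
    if (is.null(dim(slopes))) slopes <- matrix(slopes, nrow = 1)
    # slopes: n_channels x n_feasible
    hfd_sum[feasible] <- hfd_sum[feasible] + colMeans(slopes)
    spread_sum[feasible] <- spread_sum[feasible] +
      apply(slopes, 2, function(v) max(v) - min(v))
    n_used[feasible] <- n_used[feasible] + 1L
  }
  if (skipped)
    warning("some recordings were too short for the largest k_max ",
            "candidates and were skipped for those candidates",
            call. = FALSE)
  if (all(n_used == 0)) stop_hfd("no recording is long enough for any candidate")
  out <- data.frame(k_max = candidates,
                    mean_hfd = ifelse(n_used > 0, hfd_sum / n_used, NA),
                    mean_spread = ifelse(n_used > 0, spread_sum / n_used, NA),
                    n_recordings = n_used)
  class(out) <- c("kmax_sweep", "data.frame")
  out
}

#' Select k_max from a sweep
#'
#' Dual criterion: take the candidate maximizing the mean channel spread;
#' among all candidates whose spread is within `plateau_tol` (relative) of
#' that maximum, prefer the smallest one at which the mean HFD has begun
#' to plateau — i.e. lies within `plateau_tol` (relative) of the final
#' candidate's mean HFD. If no near-maximal candidate has plateaued, the
#' spread maximizer itself is returned. Ties break toward the smaller
#' k_max. Candidate order in the input is irrelevant (sorted internally).
#'
#' @param sweep a `kmax_sweep` from [sweep_kmax()] (or any data frame with
#'   `k_max`, `mean_hfd`, `mean_spread`).
#' @param plateau_tol relative tolerance for both the spread near-maximum
#'   and the mean-HFD plateau (default 0.02).
#' @return The selected k_max (integer, always one of the candidates).
#' @export
select_kmax <- function(sweep, plateau_tol = 0.02) {
  sweep <- sweep[!is.na(sweep$mean_spread) & !is.na(sweep$mean_hfd), ,
                 drop = FALSE]
  if (!nrow(sweep)) stop_hfd("empty sweep")
  sweep <- sweep[order(sweep$k_max), , drop = FALSE]
  best_spread <- max(sweep$mean_spread)
  near <- sweep$mean_spread >= best_spread * (1 - plateau_tol)
  final_hfd <- sweep$mean_hfd[nrow(sweep)]
  plateaued <- abs(sweep$mean_hfd - final_hfd) <= plateau_tol * abs(final_hfd)
  hit <- which(near & plateaued)
  if (length(hit)) return(sweep$k_max[hit[1]])
  sweep$k_max[which.max(sweep$mean_spread)]
}
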