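# Higuchi fractal dimension (HFD).
#
# For a series x(1..N) and subsampling interval k, the k-subsampled curve
# starting at phase m (1 <= m <= k) has normalized length
#
#   L_m(k) = [ sum_{i=1..M} |x(m+ik) - x(m+(i-1)k)| ] * (N-1)/(M*k) / k,
#   M = floor((N-m)/k),
#
# L(k) = mean over the k phases, and the HFD is the slope of the ordinary
# least-squares fit of log L(k) against log(1/k) for k = 1..k_max. For
# self-affine signals L(k) ~ k^(-D), so the slope estimates the fractal
# dimension: ~1 for smooth signals, ~2 for uncorrelated noise.

#' HFD extraction parameters
#'
#' @param k_max largest subsampling interval of the log-log fit (integer,
#'   at least 2). The method's key hyperparameter; see [sweep_kmax()] /
#'   [select_kmax()] for the tuning procedure.
#' @param window_seconds optional window length in seconds. `NULL` (the
#'   default) computes one HFD over the whole signal; otherwise one HFD per
#'   complete non-overlapping window.
#' @return An object of class `hfd_params`.
#' @export
hfd_params <- function(k_max, window_seconds = NULL) {
  if (!is.numeric(k_max) || length(k_max) != 1 || k_max < 2 ||
      k_max != round(k_max))
    stop_hfd("k_max must be a single integer >= 2")
  if (!is.null(window_seconds) && window_seconds <= 0)
    stop_hfd("window_seconds must be positive")
  structure(list(k_max = as.integer(k_max),
                 window_seconds = window_seconds),
            class = "hfd_params")
}

#' Normalized curve length for one phase offset
#'
#' `L_m(k)` of the canonical Higuchi construction (see the formula at the
#' top of this file). Zero if and only if the k-subsampled sequence
#' starting at `m` is constant.
#'
#' @param x numeric vector, length at least 2.
#' @param m start phase, `1 <= m <= k`.
#' @param k subsampling interval, `k <= length(x) - 1`.
#' @return Non-negative scalar.
#' @examples
#' curve_length_m(0:5, m = 1, k = 1)  # 5
#' curve_length_m(0:5, m = 1, k = 2)  # 2.5
#' @export
curve_length_m <- function(x, m, k) {
  n <- length(x)
  if (n < 2) stop_hfd("index contract violated: need at least 2 samples")
  if (m < 1 || k < 1 || m > k || k > n - 1)
    stop_hfd("index contract violated: need 1 <= m <= k <= length(x) - 1 ",
             "(m = ", m, ", k = ", k, ", N = ", n, ")")
  M <- (n - m) %/% k
  idx <- m + (0:M) * k
  sum(abs(diff(x[idx]))) * (n - 1) / (M * k) / k
}

#' Average normalized curve length L(k)
#'
#' Arithmetic mean of [curve_length_m()] over the `k` phase offsets
#' `m = 1..k`.
#'
#' @inheritParams curve_length_m
#' @return Non-negative scalar.
#' @export
curve_length <- function(x, k) {
  mean(vapply(seq_len(k), function(m) curve_length_m(x, m, k), numeric(1)))
}

# Slope of log(L) against log(1/k) for k = 1..k_max (natural log; the slope
# is log-base invariant). Errors on zero lengths (degenerate signal).
fit_hfd_slope <- function(L) {
  if (anyNA(L) || any(L <= 0))
    stop_hfd("degenerate signal: zero curve length (constant or too-short ",
             "subsampled sequence); HFD is undefined")
  k <- seq_along(L)
  lx <- log(1 / k); ly <- log(L)
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

#' Higuchi fractal dimension of a signal
#'
#' @param x numeric vector, length at least `2 * k_max`, not constant.
#' @param k_max largest subsampling interval (every integer `1..k_max` is
#'   used in the fit).
#' @return The HFD estimate (slope of the log-log fit); approximately in
#'   `[1, 2]` for self-affine signals.
#' @examples
#' higuchi_fd(seq_len(1000), 8)          # linear ramp -> 1
#' higuchi_fd(rnorm(4096), 8)            # white noise -> about 2
#' @export
higuchi_fd <- function(x, k_max) {
  k_max <- as.integer(k_max)
  if (k_max < 2) stop_hfd("k_max must be at least 2")
  if (length(x) < 2 * k_max)
    stop_hfd("signal too short: need length >= 2 * k_max = ", 2 * k_max,
             ", got ", length(x))
  if (!all(is.finite(x))) stop_hfd("signal contains non-finite values")
  fit_hfd_slope(cpp_higuchi_lengths(as.numeric(x), k_max))
}

#' Reference (naive) Higuchi fractal dimension
#'
#' Plain-R triple-loop implementation built directly from
#' [curve_length_m()] / [curve_length()], kept as an independent reference
#' for validating the optimized estimator. Identical contract to
#' [higuchi_fd()].
#'
#' @inheritParams higuchi_fd
#' @return The HFD estimate.
#' @export
higuchi_fd_naive <- function(x, k_max) {
  k_max <- as.integer(k_max)
  if (k_max < 2) stop_hfd("k_max must be at least 2")
  if (length(x) < 2 * k_max)
    stop_hfd("signal too short: need length >= 2 * k_max = ", 2 * k_max,
             ", got ", length(x))
  fit_hfd_slope(vapply(seq_len(k_max), function(k) curve_length(x, k),
                       numeric(1)))
}

#' Windowed Higuchi fractal dimension
#'
#' One HFD per complete non-overlapping window of `window_seconds`, in
#' temporal order; a trailing partial window is discarded. Windowing is
#' advised for nonstationary signals, where a single whole-signal HFD is
#' not representative.
#'
#' @inheritParams higuchi_fd
#' @param window_seconds window length in seconds.
#' @param sampling_rate sampling rate in Hz.
#' @return Numeric vector, one HFD per complete window.
#' @export
windowed_hfd <- function(x, window_seconds, sampling_rate, k_max) {
  wlen <- floor(window_seconds * sampling_rate)
  if (wlen < 2 * k_max)
    stop_hfd("window too short: ", wlen, " samples but need >= 2 * k_max = ",
             2 * k_max)
  n_win <- length(x) %/% wlen
  if (n_win < 1)
    stop_hfd("empty result: signal shorter than one window (",
             length(x), " < ", wlen, " samples)")
  vapply(seq_len(n_win), function(w)
    higuchi_fd(x[((w - 1) * wlen + 1):(w * wlen)], k_max), numeric(1))
}

#' Extract HFD features from a cohort
#'
#' Computes the HFD of every non-auxiliary channel of every recording in
#' the manifest (auxiliary ocular/cardiac channels are excluded), either
#' whole-signal or windowed per `params`.
#'
#' @param cohort an `eeg_cohort` from [generate_cohort()] /
#'   [read_cohort()].
#' @param params an [hfd_params()].
#' @param conditions which conditions to extract (default both task and
#'   rest).
#' @param verbose print a progress line per recording.
#' @return A long-format data frame of class `hfd_table` with columns
#'   `subject_id`, `group`, `condition`, `presentation_id`, `channel`,
#'   `window` (0 for whole-signal), `hfd`; the `hfd_params` used are
#'   attached as attribute `params`.
#' @export
extract_features <- function(cohort, params,
                             conditions = c("task", "rest"),
                             verbose = FALSE) {
  stopifnot(inherits(params, "hfd_params"))
  rec_index <- cohort$manifest$recordings
  rec_index <- rec_index[rec_index$condition %in% conditions, , drop = FALSE]
  eeg <- eeg_channels(cohort$montage)
  out <- vector("list", nrow(rec_index))
  for (i in seq_len(nrow(rec_index))) {
    row <- rec_index[i, ]
    r <- get_recording(cohort, row$subject_id, row$condition,
                       row$presentation_id)
    if (verbose)
      message(sprintf("extracting %s/%s", row$subject_id,
                      if (is.na(row$presentation_id)) "rest"
                      else row$presentation_id))
    sig <- r$signal[match(eeg, r$montage$channel_names), , drop = FALSE]
    vals <- if (is.null(params$window_seconds)) {
      matrix(apply(sig, 1, higuchi_fd, k_max = params$k_max), nrow = 1)
    } else {
      apply(sig, 1, windowed_hfd, window_seconds = params$window_seconds,
            sampling_rate = r$sampling_rate, k_max = params$k_max)
    }
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
    n_win <- nrow(vals)
    win_idx <- if (is.null(params$window_seconds)) 0L else seq_len(n_win)
    out[[i]] <- data.frame(
      subject_id = row$subject_id, group = row$group,
      condition = row$condition, presentation_id = row$presentation_id,
      channel = rep(eeg, each = n_win),
      window = rep(win_idx, times = length(eeg)),
      hfd = as.vector(vals), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!all(is.finite(res$hfd)))
    stop_hfd("non-finite HFD value produced; degenerate recording?")
  attr(res, "params") <- params
  class(res) <- c("hfd_table", "data.frame")
  res
}
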