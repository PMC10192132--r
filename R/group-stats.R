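# Channel-level group contrasts.
#
# The per-channel contrast is the double mean: HFD averaged over
# presentations (and windows) within a subject, then over subjects within
# a group; the contrast is the difference of the two group means. Tests
# are two-sample t-tests on the subject-level means (subjects, not
# subject-presentation pairs, are the units of analysis — this avoids
# pseudo-replication across the 16 presentations of one subject).

# Per (subject, channel) mean HFD; rows restricted to one condition and
# optionally a subset of presentations. Returns subjects x channels matrix.
subject_channel_means <- function(features, condition = "task",
                                  presentations = NULL) {
  f <- features[features$condition == condition, , drop = FALSE]
  if (!is.null(presentations))
    f <- f[f$presentation_id %in% presentations, , drop = FALSE]
  if (!nrow(f)) stop_hfd("no feature rows for condition '", condition, "'")
  channels <- unique(f$channel)
  m <- tapply(f$hfd, list(f$subject_id, f$channel), mean)
  m[, channels, drop = FALSE]
}

group_of_subjects <- function(features) {
  u <- unique(features[, c("subject_id", "group")])
  setNames(u$group, u$subject_id)
}

#' Per-channel group difference of mean HFD
#'
#' For each non-auxiliary channel: mean HFD of `group_a` minus mean HFD of
#' `group_b`, where each group mean is the mean over subjects of the
#' per-subject mean over presentations.
#'
#' @param features an `hfd_table`.
#' @param group_a,group_b group labels (default expert minus novice).
#' @param presentations optional subset of presentation ids.
#' @param condition condition to contrast (default task).
#' @return Named numeric vector (one signed value per channel).
#' @export
delta_hfd <- function(features, group_a = "expert", group_b = "novice",
                      presentations = NULL, condition = "task") {
  m <- subject_channel_means(features, condition, presentations)
  grp <- group_of_subjects(features)[rownames(m)]
  if (!any(grp == group_a) || !any(grp == group_b))
    stop_hfd("both groups must be non-empty")
  if (anyNA(m))
    stop_hfd("alignment error: some channels are missing for some subjects")
  colMeans(m[grp == group_a, , drop = FALSE]) -
    colMeans(m[grp == group_b, , drop = FALSE])
}

#' Per-channel two-sample tests between groups
#'
#' Welch two-sample t-test (pooled-variance optional) per channel on
#' subject-level mean HFD, one-sided by default in the direction
#' `group_a < group_b` (novices showing higher task complexity than
#' experts when called with the defaults). Uncorrected p-values are
#' compared against `alpha`; a Benjamini-Hochberg adjusted column is
#' always emitted alongside.
#'
#' @inheritParams delta_hfd
#' @param alpha significance level (default 0.05, uncorrected).
#' @param direction `"a_less"` (default), `"a_greater"` or `"two_sided"`.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @param rank_by rank channels by absolute (default) or signed delta.
#' @return Data frame of class `channel_contrast`: `channel`, `delta`
#'   (`group_a` minus `group_b`), `t_stat`, `p_value`, `p_adj`,
#'   `significant` (uncorrected, at `alpha`), `rank`.
#' @export
channel_tests <- function(features, group_a = "expert", group_b = "novice",
                          alpha = 0.05,
                          direction = c("a_less", "a_greater", "two_sided"),
                          var_equal = FALSE, presentations = NULL,
                          condition = "task", rank_by = c("abs", "signed")) {
  direction <- match.arg(direction)
  rank_by <- match.arg(rank_by)
  m <- subject_channel_means(features, condition, presentations)
  grp <- group_of_subjects(features)[rownames(m)]
  a <- m[grp == group_a, , drop = FALSE]
  b <- m[grp == group_b, , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2)
    stop_hfd("need at least 2 subjects per group for the t-test")
  alternative <- switch(direction, a_less = "less", a_greater = "greater",
                        two_sided = "two.sided")
  res <- lapply(seq_len(ncol(m)), function(j) {
    if (var(a[, j]) == 0 && var(b[, j]) == 0)
      return(list(t = NA_real_, p = NA_real_, degenerate = TRUE))
    tt <- t.test(a[, j], b[, j], alternative = alternative,
                 var.equal = var_equal)
    list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
  })
  if (any(vapply(res, `[[`, logical(1), "degenerate")))
    warning("degenerate test (zero variance in both groups) for some ",
            "channels; their p-values are NA", call. = FALSE)
  delta <- colMeans(a) - colMeans(b)
  p <- vapply(res, `[[`, numeric(1), "p")
  key <- if (rank_by == "abs") -abs(delta) else -delta
  out <- data.frame(
    channel = colnames(m), delta = unname(delta),
    t_stat = vapply(res, `[[`, numeric(1), "t"),
    p_value = p, p_adj = p.adjust(p, "BH"),
    significant = !is.na(p) & p < alpha,
    rank = rank(key, ties.method = "first"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "direction") <- direction
  attr(out, "groups") <- c(group_a, group_b)
  class(out) <- c("channel_contrast", "data.frame")
  out
}

#' Top-ranked channels of a contrast
#'
#' The `n` channels with the largest difference (absolute by default,
#' signed optionally), each carrying its significance flag. Ties are
#' broken by channel label order (deterministic).
#'
#' @param contrasts a `channel_contrast` from [channel_tests()].
#' @param n how many channels (default 10); truncated with a warning if it
#'   exceeds the number of channels.
#' @param by `"abs"` (default) or `"signed"`.
#' @return The top rows, ordered by decreasing difference.
#' @export
top_channels <- function(contrasts, n = 10, by = c("abs", "signed")) {
  by <- match.arg(by)
  if (n > nrow(contrasts)) {
    warning("n = ", n, " exceeds the ", nrow(contrasts),
            " available channels; truncating", call. = FALSE)
    n <- nrow(contrasts)
  }
  key <- if (by == "abs") -abs(contrasts$delta) else -contrasts$delta
  ord <- order(key, contrasts$channel)
  head(contrasts[ord, , drop = FALSE], n)
}

#' Algebraic-versus-geometric style contrast within one group
#'
#' Per channel, within the given group: each subject's mean HFD over
#' algebraic-style presentations minus their mean over geometric-style
#' presentations, tested with a paired (one-sample-on-differences) t-test
#' across subjects, two-sided.
#'
#' @param features an `hfd_table`.
#' @param group group to analyse (default expert).
#' @param style_a,style_g style codes (defaults `"A"`, `"G"`; a
#'   presentation's style is the trailing letter of its id).
#' @param alpha significance level.
#' @return Data frame of class `channel_contrast`: `channel`, `delta`
#'   (A minus G), `t_stat`, `p_value`, `p_adj`, `significant`.
#' @export
style_contrast <- function(features, group = "expert", style_a = "A",
                           style_g = "G", alpha = 0.05) {
  f <- features[features$condition == "task" & features$group == group, ,
                drop = FALSE]
  if (!nrow(f)) stop_hfd("no task rows for group '", group, "'")
  style <- substring(f$presentation_id, nchar(f$presentation_id))
  mA <- subject_channel_means(f[style == style_a, , drop = FALSE])
  mG <- subject_channel_means(f[style == style_g, , drop = FALSE])
  common <- intersect(rownames(mA), rownames(mG))
  dropped <- setdiff(union(rownames(mA), rownames(mG)), common)
  if (length(dropped))
    warning("subjects missing one style excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  if (length(common) < 2)
    stop_hfd("need at least 2 subjects with both styles")
  d <- mA[common, , drop = FALSE] - mG[common, colnames(mA), drop = FALSE]
  res <- lapply(seq_len(ncol(d)), function(j) {
    if (var(d[, j]) == 0) return(list(t = NA_real_, p = NA_real_))
    tt <- t.test(d[, j])
    list(t = unname(tt$statistic), p = tt$p.value)
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  out <- data.frame(channel = colnames(d), delta = unname(colMeans(d)),
                    t_stat = vapply(res, `[[`, numeric(1), "t"),
                    p_value = p, p_adj = p.adjust(p, "BH"),
                    significant = !is.na(p) & p < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "groups") <- c(style_a, style_g)
  class(out) <- c("channel_contrast", "data.frame")
  out
}

#' Export contrast values for topographic plotting
#'
#' A (channel, delta, p_value) table in montage order, suitable for any
#' scalp-topography plotting tool; rendering itself is out of scope here.
#'
#' @param contrasts a `channel_contrast`.
#' @param montage the `montage_spec` the features came from.
#' @return Data frame with one row per non-auxiliary montage channel, in
#'   montage order.
#' @export
export_topography <- function(contrasts, montage) {
  eeg <- eeg_channels(montage)
  miss <- setdiff(eeg, contrasts$channel)
  if (length(miss))
    stop_hfd("contrasts are missing montage channels: ",
             paste(head(miss, 5), collapse = ", "))
  idx <- match(eeg, contrasts$channel)
  data.frame(channel = eeg, delta = contrasts$delta[idx],
             p_value = contrasts$p_value[idx], stringsAsFactors = FALSE)
}
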