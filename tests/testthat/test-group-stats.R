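# Hand-built table: 2 subjects per group, 2 presentations, 1 channel.
# Expert values {1.6, 1.8 | 1.5, 1.7}, novice {1.4, 1.6 | 1.3, 1.5}:
# subject means 1.7, 1.6 vs 1.5, 1.4 -> double mean 1.65 - 1.45 = 0.2.
two_group_table <- function() {
  manual_hfd_table(
    subject_id = rep(c("e1", "e2", "n1", "n2"), each = 2),
    group = rep(c("expert", "novice"), each = 4),
    presentation_id = rep(c("1A", "1G"), 4),
    channel = "c1",
    hfd = c(1.6, 1.8, 1.5, 1.7, 1.4, 1.6, 1.3, 1.5))
}

test_that("delta HFD is the difference of double means", {
  expect_equal(unname(delta_hfd(two_group_table())), 0.2)

  # identical groups -> exactly zero
  tbl <- manual_hfd_table(
    subject_id = rep(c("e1", "e2", "n1", "n2"), each = 2),
    group = rep(c("expert", "novice"), each = 4),
    presentation_id = rep(c("1A", "1G"), 4),
    channel = "c1", hfd = rep(c(1.5, 1.7), 4))
  expect_equal(unname(delta_hfd(tbl)), 0)
})

test_that("delta HFD is antisymmetric in the group order", {
  f <- small_features(seed = 21, n_subjects = 3, n_pairs = 1)
  d_en <- delta_hfd(f, "expert", "novice")
  d_ne <- delta_hfd(f, "novice", "expert")
  expect_equal(d_en, -d_ne)
})

test_that("channel tests flag the configured effect channels", {
  f <- small_features(seed = 31, n_subjects = 10, n_pairs = 1,
                      effect_delta_fd = 0.2, subject_sd = 0.02,
                      sampling_rate = 256, duration = c(6, 7), k_max = 20)
  ct <- channel_tests(f)                     # expert < novice one-sided
  expect_s3_class(ct, "channel_contrast")
  expect_setequal(ct$rank, seq_len(nrow(ct)))
  expect_true(all(ct$p_value >= 0 & ct$p_value <= 1))
  expect_identical(ct$significant, !is.na(ct$p_value) &
                     ct$p_value < attr(ct, "alpha"))
  eff <- ct[ct$channel %in% c("X1", "X2"), ]
  expect_true(all(eff$significant))
  expect_true(all(eff$delta < 0))            # expert minus novice
  # the effect channels carry the largest absolute differences
  expect_setequal(top_channels(ct, 2)$channel, c("X1", "X2"))
})

test_that("top channels are deterministic under ties and truncate with warning", {
  tbl <- data.frame(channel = c("b", "a", "c"), delta = c(0.2, 0.2, 0.1),
                    t_stat = 1, p_value = 0.5, p_adj = 0.5,
                    significant = FALSE, rank = 1:3)
  class(tbl) <- c("channel_contrast", "data.frame")
  expect_equal(top_channels(tbl, 2)$channel, c("a", "b"))  # label order tie-break
  expect_equal(top_channels(tbl, 1)$channel, "a")
  expect_warning(all3 <- top_channels(tbl, 10), "truncat")
  expect_equal(nrow(all3), 3)
})

test_that("style contrast recovers constructed A-vs-G differences", {
  # A values = G values + 0.1 on channel c1, equal on c2
  subjects <- c("e1", "e2", "e3")
  tbl <- manual_hfd_table(
    subject_id = rep(subjects, each = 4),
    group = "expert",
    presentation_id = rep(c("1A", "2A", "1G", "2G"), 3),
    channel = "c1",
    hfd = rep(c(1.62, 1.58, 1.52, 1.48), 3) + rep(c(0, 0.01, 0.02), each = 4))
  tbl2 <- tbl; tbl2$channel <- "c2"
  tbl2$hfd <- rep(c(1.5, 1.5, 1.5, 1.5), 3) + rep(c(0, 0.01, 0.02), each = 4)
  sc <- style_contrast(rbind(tbl, tbl2))
  expect_equal(sc$delta[sc$channel == "c1"], 0.1, tolerance = 1e-12)
  expect_equal(sc$delta[sc$channel == "c2"], 0, tolerance = 1e-12)

  # swapping the style labels negates the contrast exactly
  sc_swap <- style_contrast(rbind(tbl, tbl2), style_a = "G", style_g = "A")
  expect_equal(sc_swap$delta, -sc$delta)
})

test_that("no style effect exists in the generated cohorts", {
  f <- small_features(seed = 41, n_subjects = 8, n_pairs = 2)
  sc <- style_contrast(f)
  # generator draws A and G signals identically: at most chance-level hits
  expect_lte(sum(sc$significant), qbinom(0.999, nrow(sc), 0.05))
})

test_that("topography export preserves montage order and values", {
  f <- small_features(seed = 51, n_subjects = 3, n_pairs = 1)
  ct <- channel_tests(f)
  topo <- export_topography(ct, small_montage())
  expect_equal(topo$channel, eeg_channels(small_montage()))
  expect_equal(nrow(topo), 16)
  idx <- match(topo$channel, ct$channel)
  expect_equal(topo$delta, ct$delta[idx])
  expect_equal(topo$p_value, ct$p_value[idx])
})

test_that("degenerate zero-variance channels are flagged, not fatal", {
  tbl <- two_group_table()
  flat <- tbl; flat$channel <- "c2"; flat$hfd <- 1.5
  expect_warning(ct <- channel_tests(rbind(tbl, flat)), "degenerate")
  expect_true(is.na(ct$p_value[ct$channel == "c2"]))
  expect_false(is.na(ct$p_value[ct$channel == "c1"]))
})
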