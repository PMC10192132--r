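test_that("montage invariants are enforced", {
  m <- default_montage()
  expect_length(m$channel_names, 129)
  expect_length(eeg_channels(m), 124)
  expect_length(m$auxiliary_names, 5)
  expect_setequal(m$auxiliary_names,
                  c("VEOGL", "HEOGL", "HEOGR", "VEOGU", "HEART"))
  expect_length(m$standard32_names, 32)
  expect_true(all(m$standard32_names %in% eeg_channels(m)))

  expect_error(montage_spec(c("A", "A", "B")), "duplicate")
  expect_error(montage_spec(c("A", "B"), auxiliary_names = "C"), "subset")
  expect_error(montage_spec(c("A", "B"), auxiliary_names = "B",
                            standard32_names = "B"), "subset")
})

test_that("cohort configuration validates its parameters", {
  expect_error(cohort_config(baseline_fd = 2.1), "strictly in")
  expect_error(cohort_config(baseline_fd = 1.9, effect_delta_fd = 0.2),
               "strictly in")
  expect_error(cohort_config(duration_range = c(-1, 5)), "positive")
  expect_error(cohort_config(sampling_rate = 0), "positive")
  expect_error(build_manifest(cohort_config(effect_channels = "NOPE")),
               "configuration error")
  expect_error(generate_recording("s", "expert", "task", "1A", 4,
                                  small_config(effect_channels = "NOPE"),
                                  small_montage(), seed = 1),
               "configuration error")
})

test_that("the manifest has the study's structure", {
  # default configuration: 44 subjects x 16 presentations task recordings
  m <- build_manifest(cohort_config())
  task <- m$recordings[m$recordings$condition == "task", ]
  expect_equal(nrow(task), 704)
  expect_equal(nrow(m$recordings[m$recordings$condition == "rest", ]), 44)
  expect_equal(nrow(m$presentations), 16)
  expect_equal(sum(m$presentations$style == "A"), 8)

  # durations: identical across subjects for a presentation, matched
  # within each A/G pair, inside the configured range
  durs <- tapply(task$duration, task$presentation_id,
                 function(d) length(unique(d)))
  expect_true(all(durs == 1))
  p <- m$presentations
  expect_equal(p$duration[p$presentation_id == "3A"],
               p$duration[p$presentation_id == "3G"])
  expect_true(all(p$duration >= 13 & p$duration <= 68))

  # tiny cohort counting
  m2 <- build_manifest(small_config(n_subjects = 2, n_pairs = 1),
                       small_montage())
  expect_equal(sum(m2$recordings$condition == "task"), 8)
  expect_equal(sum(m2$recordings$condition == "rest"), 4)
})

test_that("cohorts are byte-reproducible from (config, seed)", {
  c1 <- small_cohort(seed = 5, n_subjects = 2, n_pairs = 1)
  c2 <- small_cohort(seed = 5, n_subjects = 2, n_pairs = 1)
  expect_identical(c1$manifest, c2$manifest)
  r1 <- get_recording(c1, "novice01", "task", "1G")
  r2 <- get_recording(c2, "novice01", "task", "1G")
  expect_identical(r1$signal, r2$signal)
  # different master seed changes the signals
  c3 <- small_cohort(seed = 6, n_subjects = 2, n_pairs = 1)
  expect_false(identical(get_recording(c3, "novice01", "task", "1G")$signal,
                         r1$signal))
})

test_that("the group effect is present in task and absent at rest", {
  # effect_delta_fd = +0.2 for novices on X1/X2: novice task HFD on the
  # effect channels exceeds expert task HFD; rest shows no such shift.
  cohort <- small_cohort(seed = 8, n_subjects = 4, n_pairs = 1,
                         effect_delta_fd = 0.2, subject_sd = 0)
  f <- extract_features(cohort, hfd_params(20), conditions = c("task", "rest"))
  eff <- f$channel %in% c("X1", "X2")
  task <- f$condition == "task"; nov <- f$group == "novice"
  expect_gt(mean(f$hfd[eff & task & nov]), mean(f$hfd[eff & task & !nov]) + 0.05)
  expect_lt(abs(mean(f$hfd[eff & !task & nov]) -
                mean(f$hfd[eff & !task & !nov])), 0.05)
  # non-effect channels carry no group difference during task
  expect_lt(abs(mean(f$hfd[!eff & task & nov]) -
                mean(f$hfd[!eff & task & !nov])), 0.05)
})

test_that("recording matrices have the declared geometry", {
  cfg <- small_config(n_subjects = 2, n_pairs = 1, duration = c(6, 6))
  r <- generate_recording("expert01", "expert", "task", "1A", 6, cfg,
                          small_montage(), seed = 99)
  expect_equal(dim(r$signal), c(18, round(6 * cfg$sampling_rate)))
  expect_true(all(is.finite(r$signal)))
  expect_equal(rowMeans(r$signal), rep(0, 18), tolerance = 1e-9,
               ignore_attr = TRUE)
})
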