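test_that("sample assembly yields one row per subject-presentation pair", {
  f <- small_features(seed = 61, n_subjects = 3, n_pairs = 2)
  s <- assemble_samples(f)
  expect_s3_class(s, "sample_table")
  expect_equal(nrow(s), 6 * 4)
  expect_equal(ncol(s) - 3, 16)             # feature columns = EEG channels
  expect_setequal(unique(s$label), c("expert", "novice"))

  s32 <- assemble_samples(f, small_montage(), channel_set = "standard32")
  expect_equal(ncol(s32) - 3, 8)
  expect_true(all(startsWith(setdiff(colnames(s32),
                                     c("subject_id", "presentation_id",
                                       "label")), "S")))
})

test_that("windowed assembly multiplies features by window count", {
  cohort <- small_cohort(seed = 62, n_subjects = 2, n_pairs = 1,
                         duration = c(8, 8))
  f <- extract_features(cohort, hfd_params(8, window_seconds = 2),
                        conditions = "task")
  s <- assemble_samples(f, presentations = "1A", windowed = TRUE)
  expect_equal(nrow(s), 4)
  expect_equal(ncol(s) - 3, 16 * 4)          # (T / N) x channels

  # mixing presentations of different window counts is rejected by name
  f_bad <- f
  f_bad <- f_bad[!(f_bad$presentation_id == "1G" & f_bad$window == 4), ]
  expect_error(assemble_samples(f_bad, windowed = TRUE),
               "inconsistent window counts.*1G|1A")
  # whole-signal tables refuse windowed assembly and vice versa
  expect_error(assemble_samples(f, windowed = FALSE), "windowed")
})

test_that("split plans partition rows and respect subject boundaries", {
  f <- small_features(seed = 63, n_subjects = 5, n_pairs = 2)
  s <- assemble_samples(f)                  # 10 subjects x 4 presentations

  plan <- make_split(s, "subject_presentation", n_folds = 5, seed = 1)
  val <- sort(unlist(lapply(plan$folds, `[[`, "validation")))
  expect_equal(val, seq_len(nrow(s)))       # folds partition all rows
  for (fold in plan$folds) {
    expect_length(intersect(fold$train, fold$validation), 0)
    expect_setequal(c(fold$train, fold$validation), seq_len(nrow(s)))
  }

  plan2 <- make_split(s, "subject_specific", n_folds = 5, seed = 1)
  val2 <- sort(unlist(lapply(plan2$folds, `[[`, "validation")))
  expect_equal(val2, seq_len(nrow(s)))
  for (fold in plan2$folds)
    expect_length(intersect(unique(s$subject_id[fold$train]),
                            unique(s$subject_id[fold$validation])), 0)

  plan3 <- make_split(s, "presentation_specific", n_folds = 5, seed = 1,
                      presentation_id = "2A")
  rows3 <- unlist(lapply(plan3$folds, `[[`, "validation"))
  expect_length(rows3, 10)                  # one row per subject
  expect_true(all(s$presentation_id[rows3] == "2A"))

  expect_error(make_split(s, "subject_specific", n_folds = 20, seed = 1),
               "exceeds")
  expect_error(make_split(s, "presentation_specific", n_folds = 2, seed = 1),
               "presentation_id is required")
  expect_error(make_split(s, "subject_specific", n_folds = 2, seed = 1,
                          presentation_id = "1A"), "only meaningful")
})

test_that("fold validation sizes are balanced partition arithmetic", {
  # 704 rows in 10 folds -> validation sizes 70 or 71; split plans only
  # need the identity columns, so the table is built directly.
  s <- data.frame(subject_id = rep(sprintf("s%02d", 1:44), each = 16),
                  presentation_id = rep(sprintf("%d%s", rep(1:8, each = 2),
                                                c("A", "G")), 44),
                  label = rep(c("expert", "novice"), each = 352))
  class(s) <- c("sample_table", "data.frame")
  plan <- make_split(s, "subject_presentation", n_folds = 10, seed = 3)
  sizes <- vapply(plan$folds, function(f) length(f$validation), integer(1))
  expect_setequal(unique(sizes), c(70, 71))
  expect_equal(sum(sizes), 704)
  p7 <- make_split(s, "presentation_specific", n_folds = 10, seed = 3,
                   presentation_id = "7A")
  expect_length(unlist(lapply(p7$folds, `[[`, "validation")), 44)
})

test_that("the AdaBoost learner separates separable data", {
  set.seed(5)
  x <- matrix(rnorm(120), 60, 2)
  y <- factor(ifelse(x[, 1] + 0.2 * rnorm(60) > 0, "expert", "novice"))
  fit <- ada_fit(x, y, 25)
  expect_gt(mean(predict(fit, x) == y), 0.9)
  # single-class degenerate input falls back to the majority vote
  y1 <- factor(rep("expert", 60), levels = c("expert", "novice"))
  fit1 <- ada_fit(x, y1, 10)
  expect_true(all(predict(fit1, x) == "expert"))
})

test_that("a strong localized effect is learnable under every algorithm family", {
  # study-like durations and the selected k_max = 100, where the effect
  # expresses as a clear per-sample feature shift
  f <- small_features(seed = 64, n_subjects = 8, n_pairs = 1,
                      effect_delta_fd = 0.2, subject_sd = 0.02,
                      sampling_rate = 256, duration = c(13, 14), k_max = 100)
  s <- assemble_samples(f)
  grid <- list(nearest_neighbors = list(param = "n_neighbors", values = 3),
               linear_svm = list(param = "cost", values = 0.5),
               decision_tree = list(param = "max_depth", values = 3),
               adaboost = list(param = "n_estimators", values = 25))
  rep <- run_grid(s, "subject_presentation", grid, seeds = 0, n_folds = 5)
  expect_true(all(rep$accuracy > 0.6))
  expect_gte(max(rep$accuracy), 0.9)
})

test_that("reports are reproducible and summarized correctly", {
  f <- small_features(seed = 65, n_subjects = 4, n_pairs = 1)
  s <- assemble_samples(f)
  grid <- list(linear_svm = list(param = "cost", values = c(0.025, 0.5)))
  r1 <- run_grid(s, "subject_specific", grid, seeds = c(0, 1), n_folds = 4)
  r2 <- run_grid(s, "subject_specific", grid, seeds = c(0, 1), n_folds = 4)
  expect_identical(r1, r2)

  # best_per_scheme is the max of the per-algorithm seed means
  rep <- data.frame(scheme = "subject_presentation",
                    algorithm = c("a", "b", "c"),
                    presentation = NA_character_, seed = 0,
                    accuracy = c(0.6, 0.7, 0.65))
  class(rep) <- c("accuracy_report", "data.frame")
  best <- best_per_scheme(rep)
  expect_equal(best$algorithm, "b")
  expect_equal(best$mean_accuracy, 0.7)
  # ties: all tied algorithms reported
  rep$accuracy <- c(0.7, 0.7, 0.6)
  expect_setequal(best_per_scheme(rep)$algorithm, c("a", "b"))
})
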