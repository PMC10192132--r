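test_that("curve lengths match hand-computed values", {
  x <- c(0, 1, 2, 3, 4, 5)
  # m=1, k=1: M=5, sum|diff|=5, *(5/5)/1 = 5
  expect_equal(curve_length_m(x, 1, 1), 5)
  # m=1, k=2: M=2, |x3-x1|+|x5-x3| = 4, *(5/(2*2))/2 = 2.5
  expect_equal(curve_length_m(x, 1, 2), 2.5)
  # m=2, k=2: M=2, |x4-x2|+|x6-x4| = 4, *(5/(2*2))/2 = 2.5
  expect_equal(curve_length_m(x, 2, 2), 2.5)
  expect_equal(curve_length_m(rep(3, 10), 1, 2), 0)

  expect_equal(curve_length(x, 1), 5)
  expect_equal(curve_length(x, 2), mean(c(2.5, 2.5)))

  # independent scalar-loop oracle for a non-trivial signal
  set.seed(11)
  y <- rnorm(40)
  oracle <- function(y, m, k) {
    n <- length(y); M <- floor((n - m) / k); s <- 0
    for (i in 1:M) s <- s + abs(y[m + i * k] - y[m + (i - 1) * k])
    s * (n - 1) / (M * k) / k
  }
  for (k in 1:5) {
    lm_vals <- sapply(1:k, function(m) oracle(y, m, k))
    expect_equal(curve_length(y, k), mean(lm_vals), tolerance = 1e-14)
  }
})

test_that("curve length is homogeneous in amplitude", {
  set.seed(2)
  x <- rnorm(100)
  for (k in c(1, 3, 7))
    expect_equal(curve_length(3 * x, k), 3 * curve_length(x, k),
                 tolerance = 1e-12)
})

test_that("index contracts are enforced", {
  x <- rnorm(50)
  expect_error(curve_length_m(x, 3, 2), "index contract")
  expect_error(curve_length_m(x, 1, 50), "index contract")
  expect_error(curve_length_m(c(1), 1, 1), "at least 2")
  expect_error(higuchi_fd(x, 30), "too short")
  expect_error(higuchi_fd(rep(1, 100), 8), "degenerate")
  expect_error(higuchi_fd_naive(rep(1, 100), 8), "degenerate")
})

test_that("known signals have known fractal dimensions", {
  # ramp: L(k) proportional to 1/k exactly up to floor effects -> slope 1
  expect_equal(higuchi_fd(seq_len(1000), 8), 1, tolerance = 0.01)
  # Gaussian white noise -> dimension 2
  est <- vapply(1:20, function(s) {
    set.seed(s)
    higuchi_fd(rnorm(8192), 8)
  }, numeric(1))
  expect_lt(abs(mean(est) - 2), 0.05)
})

test_that("the optimized estimator matches the naive reference exactly", {
  set.seed(42)
  for (i in 1:20) {
    x <- cumsum(rnorm(150))
    expect_equal(higuchi_fd(x, 10), higuchi_fd_naive(x, 10),
                 tolerance = 1e-12)
  }
})

test_that("HFD is invariant under affine transforms of the signal", {
  set.seed(9)
  x <- cumsum(rnorm(500))
  h <- higuchi_fd(x, 12)
  expect_equal(higuchi_fd(2.5 * x + 100, 12), h, tolerance = 1e-10)
  expect_equal(higuchi_fd(-x, 12), h, tolerance = 1e-10)
})

test_that("windowed HFD yields one value per complete window", {
  fs <- 64
  x <- synthesize_fractal_signal(40 * fs, 1.5, fs, seed = 1)
  expect_length(windowed_hfd(x, 8, fs, 8), 5)     # floor(40/8)
  expect_length(windowed_hfd(x[1:(13 * fs)], 11, fs, 8), 1)
  expect_error(windowed_hfd(x[1:100], 8, fs, 8), "empty result")
  expect_error(windowed_hfd(x, 0.1, fs, 8), "window too short")

  # stationarity: windowed mean close to whole-signal value
  est_w <- mean(windowed_hfd(x, 8, fs, 8))
  expect_lt(abs(est_w - higuchi_fd(x, 8)), 0.1)
})

test_that("feature extraction covers every recording and EEG channel", {
  cohort <- small_cohort(seed = 3)
  f <- extract_features(cohort, hfd_params(8))
  eeg <- eeg_channels(cohort$montage)
  n_rec <- nrow(cohort_recordings(cohort))
  expect_s3_class(f, "hfd_table")
  expect_equal(nrow(f), n_rec * length(eeg))
  expect_setequal(unique(f$channel), eeg)
  expect_false(any(f$channel %in% cohort$montage$auxiliary_names))
  expect_true(all(is.finite(f$hfd)))
  expect_equal(attr(f, "params")$k_max, 8L)
  # one rest feature vector per subject
  rest <- f[f$condition == "rest", ]
  expect_equal(nrow(rest), nrow(cohort$manifest$subjects) * length(eeg))
  # determinism
  f2 <- extract_features(cohort, hfd_params(8))
  expect_identical(f$hfd, f2$hfd)
})

test_that("windowed extraction indexes windows in temporal order", {
  cohort <- small_cohort(seed = 4, n_subjects = 2, n_pairs = 1,
                         duration = c(8, 8))
  f <- extract_features(cohort, hfd_params(8, window_seconds = 2),
                        conditions = "task")
  expect_setequal(unique(f$window), 1:4)     # 8 s / 2 s windows
  one <- f[f$subject_id == "expert01" & f$presentation_id == "1A" &
             f$channel == "S1", ]
  expect_equal(one$window, 1:4)
})
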