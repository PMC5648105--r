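sine_epochs <- function(freq, fs = 512, n_samp = 614, amp = 1) {
  t <- (0:(n_samp - 1)) / fs
  arr <- array(0, c(1, 1, n_samp))
  arr[1, 1, ] <- amp * sin(2 * pi * freq * t)
  epoch_set(arr, fs, -200)
}

test_that("broadband filter rejects out-of-band and keeps in-band tones", {
  out40 <- bandpass(sine_epochs(40), 0.1, 30)
  expect_lt(sd(out40$data[1, 1, ]) / sd(sine_epochs(40)$data[1, 1, ]), 0.05)
  out10 <- bandpass(sine_epochs(10), 0.1, 30)
  expect_gt(sd(out10$data[1, 1, ]) / sd(sine_epochs(10)$data[1, 1, ]), 0.95)
  expect_error(bandpass(sine_epochs(10), 30, 10), "low < high")
  expect_error(bandpass(sine_epochs(10), 0.1, 400), "Nyquist")
})

test_that("six equal sub-bands, 63 subsets and classical names enumerate", {
  bands <- enumerate_band_subsets(0.1, 30)
  expect_length(bands, 63 + 4)
  singles <- vapply(bands[1:63], function(b) nrow(b$intervals), 0L)
  expect_equal(sum(singles == 1), 6)
  expect_equal(bands[[1]]$intervals[1, ], c(0.1, 5), ignore_attr = TRUE)
  first6 <- lapply(c(1, 2, 4, 8, 16, 32), function(k) bands[[k]]$intervals)
  expect_equal(do.call(rbind, first6)[, 1], c(0.1, 5, 10, 15, 20, 25))
  expect_equal(do.call(rbind, first6)[, 2], c(5, 10, 15, 20, 25, 30))
  expect_equal(vapply(bands[64:67], `[[`, "", "name"),
               c("delta", "theta", "alpha", "beta"))
})

test_that("summing the six filtered sub-bands reconstructs the broadband signal", {
  set.seed(6)
  arr <- array(rnorm(2 * 1 * 614), c(2, 1, 614))
  ep <- epoch_set(arr, 512, -200)
  full <- bandpass(ep, 0.1, 30)
  bands <- enumerate_band_subsets(0.1, 30)
  acc <- band_filter(ep, bands[[1]])
  for (k in c(2, 4, 8, 16, 32)) acc$data <- acc$data + band_filter(ep, bands[[k]])$data
  err <- sqrt(mean((acc$data - full$data)^2)) / sqrt(mean(full$data^2))
  expect_lt(err, 0.10)
})

test_that("band-subset reconstruction error shrinks as intervals accumulate", {
  set.seed(60)
  arr <- array(rnorm(614), c(1, 1, 614))
  ep <- epoch_set(arr, 512, -200)
  full <- bandpass(ep, 0.1, 30)
  bands <- enumerate_band_subsets(0.1, 30)
  nested <- c(1, 3, 7, 15, 31, 63)   # bitmask prefixes: first k intervals
  errs <- vapply(nested, function(k) {
    sub <- band_filter(ep, bands[[k]])
    sqrt(mean((sub$data - full$data)^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 1e-8))
})

test_that("amplitude rejection is threshold-exact, masked and idempotent", {
  arr <- array(rnorm(3 * 2 * 64, sd = 5), c(3, 2, 64))
  arr[2, 1, 10] <- 80
  ep <- epoch_set(arr, 128, 0)
  rej <- reject_epochs(ep, 75)
  expect_equal(rej$trial_valid, c(TRUE, FALSE, TRUE))
  expect_equal(attr(rej, "n_rejected"), 1L)
  rej2 <- reject_epochs(rej, 75)
  expect_equal(rej2$trial_valid, rej$trial_valid)

  arr2 <- array(rnorm(3 * 2 * 64, sd = 5), c(3, 2, 64))
  arr2[abs(arr2) > 70] <- 70
  ep2 <- epoch_set(arr2, 128, 0)
  expect_true(all(reject_epochs(ep2, 75)$trial_valid))
  masked <- reject_epochs(ep2, 75, external_mask = c(TRUE, TRUE, FALSE))
  expect_equal(masked$trial_valid, c(TRUE, TRUE, FALSE))
})

test_that("std normalization yields unit per-channel std and flags constants", {
  set.seed(2)
  arr <- array(rnorm(4 * 3 * 100), c(4, 3, 100))
  arr[, 2, ] <- arr[, 2, ] * 4
  ep <- epoch_set(arr, 128, 0)
  nrm <- normalize_std(ep)
  for (ch in 1:3) {
    v <- as.numeric(nrm$data[, ch, ])
    expect_equal(sqrt(mean((v - mean(v))^2)), 1, tolerance = 1e-12)
  }
  expect_equal(nrm$data[, 2, ], ep$data[, 2, ] / attr(nrm, "channel_std")[2])
  # idempotent to fp tolerance
  nrm2 <- normalize_std(nrm)
  expect_equal(nrm2$data, nrm$data, tolerance = 1e-12)
  # constant channel flagged, left unscaled
  arr[, 3, ] <- 7
  epc <- epoch_set(arr, 128, 0)
  nc <- normalize_std(epc)
  expect_equal(attr(nc, "excluded_channels"), 3L)
  expect_equal(nc$data[, 3, ], arr[, 3, ])
})

test_that("trial aggregation uses the first n valid trials elementwise", {
  arr <- array(0, c(3, 1, 2))
  arr[1, 1, ] <- c(1, 3); arr[2, 1, ] <- c(3, 5); arr[3, 1, ] <- c(11, 13)
  ep <- epoch_set(arr, 10, 0)
  expect_equal(as.numeric(suppressWarnings(
    aggregate_trials(ep, "mean", n_stimuli = 2))), c(2, 4))
  expect_equal(as.numeric(suppressWarnings(
    aggregate_trials(ep, "max", n_stimuli = 2))), c(3, 5))
  # invalid trials are skipped, not counted
  ep$trial_valid <- c(TRUE, FALSE, TRUE)
  expect_equal(as.numeric(suppressWarnings(
    aggregate_trials(ep, "mean", n_stimuli = 2))), c(6, 8))
  expect_equal(attr(suppressWarnings(
    aggregate_trials(ep, "mean", n_stimuli = 2)), "n_used"), 2L)
  ep$trial_valid <- rep(FALSE, 3)
  ep$subject_id <- "s9"
  expect_error(aggregate_trials(ep), "no usable trials.*s9")
  ep$trial_valid <- c(TRUE, FALSE, FALSE)
  expect_warning(aggregate_trials(ep), "1 valid trial")
})

test_that("window grids respect half-open bounds and sample-rounded steps", {
  # ms-exact arithmetic at 1000 Hz: starts 200, 210, ..., 350
  g <- make_window_grid(1000, -200, 1200, 100, c(200, 450), 0.9)
  expect_equal(g$step_samp, 10L)
  expect_length(g$starts, 16)
  expect_equal(g$starts_ms[1], 200)
  expect_equal(g$starts_ms[length(g$starts)], 350)
  expect_true(all(g$starts_ms + 100 <= 450))
  # single window when W nearly fills the interval
  g1 <- make_window_grid(1000, -200, 1200, 250, c(200, 450), 0.9)
  expect_length(g1$starts, 1)
  expect_error(make_window_grid(1000, -200, 1200, 300, c(200, 450), 0.9),
               "no window")
  # at 512 Hz the step rounds down to whole samples, never below one
  g2 <- make_window_grid(512, -200, 614, 50, c(200, 450), 0.9)
  expect_equal(g2$w_samp, 26L)
  expect_equal(g2$step_samp, 2L)
  g3 <- make_window_grid(512, -200, 614, 50, c(200, 450), 0.99)
  expect_equal(g3$step_samp, 1L)
})
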