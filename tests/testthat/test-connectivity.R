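test_that("lagged correlation finds identity, delays, and rejects constants", {
  set.seed(5)
  y <- rnorm(200)
  x <- y[51:130]
  r0 <- lagged_correlation(x, y, lag_max = 10, y_start = 51)
  expect_equal(r0$r, 1.0, tolerance = 1e-12)
  expect_equal(r0$lag, 0)

  y_del <- c(rep(0, 5), y[1:195])       # y delayed by 5 samples
  r5 <- lagged_correlation(y[51:130], y_del, lag_max = 10, y_start = 51)
  expect_equal(r5$lag, 5)
  expect_gt(r5$r, 0.99)

  expect_error(lagged_correlation(rep(1, 80), y, lag_max = 10),
               "zero variance")
  expect_error(lagged_correlation(rnorm(4), rnorm(4), 1), "8 samples")
})

test_that("lag scan matches the exhaustive brute-force loop exactly", {
  set.seed(12)
  for (rep in 1:5) {
    S <- 614
    a <- rnorm(S); b <- 0.4 * c(rep(0, 7), a[1:(S - 7)]) + rnorm(S)
    grid <- make_window_grid(512, -200, S, 100, c(200, 450), 0.9)
    got <- connmaps:::lag_scan_pair_cpp(a, b, grid$starts - 1L, grid$w_samp,
                                        10L, 8L)
    want <- brute_scan(a, b, grid$starts, grid$w_samp, 10)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$lag, want$lag)
    expect_equal(got$start + 1L, want$start)
  }
})

test_that("subject connectivity equals brute force on every channel pair", {
  set.seed(13)
  n <- 4; S <- 614
  X <- matrix(rnorm(n * S), n, S)
  X[4, ] <- 0.5 * c(rep(0, 10), X[2, 1:(S - 10)]) + 0.8 * X[4, ]
  rownames(X) <- tiny_montage()$names
  grid <- make_window_grid(512, -200, S, 150, c(200, 450), 0.9)
  sc <- subject_connectivity(X, grid, lag_max_samp = 10)
  expect_equal(diag(sc$values), rep(1, n), ignore_attr = TRUE)
  # each unordered pair matches brute force; the mirror entry carries the
  # same value with the negated lag
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    want <- brute_scan(X[i, ], X[j, ], grid$starts, grid$w_samp, 10)
    expect_equal(sc$values[i, j], want$r, tolerance = 1e-10)
    expect_equal(sc$lags[i, j], want$lag)
    expect_identical(sc$values[j, i], sc$values[i, j])
    expect_identical(sc$lags[j, i], -sc$lags[i, j])
  }
  # symmetric lag range: matrix symmetric
  expect_equal(sc$values, t(sc$values), tolerance = 1e-12)
  # identical channels give off-diagonal 1
  X2 <- rbind(X[1, ], X[1, ])
  rownames(X2) <- c("A", "B")
  sc2 <- subject_connectivity(X2, grid, 10)
  expect_equal(sc2$values["A", "B"], 1.0, tolerance = 1e-12)
  # constant channel raises a named zero-variance error
  X3 <- rbind(X[1, ], 0)
  rownames(X3) <- c("O2", "Flat")
  expect_error(subject_connectivity(X3, grid, 10), "Flat")
})

test_that("noise-free planted coupling yields r = 1 at the planted lag", {
  spec <- synthetic_spec(n_per_group = 2, n_trials = 4, seed = 8,
                         erp = c(latency_ms = 300, width_ms = 80,
                                 amplitude_uv = 0),
                         artifact_rate = 0,
                         couplings = list(list(source = "P8", target = "F2",
                                               lag_ms = 20,
                                               gain_healthy = 1,
                                               gain_patient = 1)))
  ep <- generate_subject(spec, "healthy", 5L)
  avg <- aggregate_trials(ep)
  rownames(avg) <- spec$montage$names
  grid <- make_window_grid(512, -200, ncol(avg), 100, c(200, 450), 0.9)
  sc <- subject_connectivity(avg, grid, lag_max_samp = 11)
  expect_equal(sc$values["P8", "F2"], 1.0, tolerance = 1e-9)
  expect_equal(abs(sc$lags["P8", "F2"]), round(20 * 512 / 1000))
})

test_that("group maps reproduce the hand-worked Fisher example", {
  vals <- array(1, c(2, 2, 4))
  vals[1, 2, ] <- vals[2, 1, ] <- c(0.8, 0.6, 0.2, 0.4)
  dimnames(vals) <- list(c("O2", "F2"), c("O2", "F2"), NULL)
  labels <- c("healthy", "healthy", "patient", "patient")
  gm <- group_maps(vals, labels)
  expect_equal(gm$cm$healthy["O2", "F2"], 0.7)
  expect_equal(gm$cm$patient["O2", "F2"], 0.3)
  expect_equal(gm$cm_std$healthy["O2", "F2"], 0.1)
  expect_equal(gm$fisher["O2", "F2"], 0.4 / sqrt(0.02), tolerance = 1e-12)
  expect_equal(gm$fisher["O2", "F2"], 2.8284, tolerance = 1e-4)

  # identical class distributions give Fisher 0
  vals[1, 2, ] <- vals[2, 1, ] <- c(0.5, 0.7, 0.5, 0.7)
  expect_equal(group_maps(vals, labels)$fisher["O2", "F2"], 0)

  # zero dispersions with distinct means hit the floor, stay finite
  vals[1, 2, ] <- vals[2, 1, ] <- c(0.6, 0.6, 0.2, 0.2)
  f <- group_maps(vals, labels)$fisher["O2", "F2"]
  expect_true(is.finite(f))
  expect_gt(f, 1e6)
  # the literal printed denominator degenerates the same way by design
  fp <- group_maps(vals, labels, denominator = "printed")$fisher["O2", "F2"]
  expect_true(is.finite(fp))
  expect_error(group_maps(vals, c("healthy", "patient", "patient",
                                  "patient")), "2 subjects")
})

test_that("window-size selection maximizes training Fisher with small-W ties", {
  t1 <- list(values = array(c(1, 0.5, 0.5, 1), c(2, 2, 6)))
  # make one configuration clearly separable on the off-diagonal
  sep <- array(1, c(2, 2, 6))
  sep[1, 2, ] <- sep[2, 1, ] <- c(0.9, 0.8, 0.85, 0.2, 0.3, 0.25)
  labels <- rep(c("healthy", "patient"), each = 3)
  flat <- array(1, c(2, 2, 6))
  flat[1, 2, ] <- flat[2, 1, ] <- rep(c(0.5, 0.5), 3)
  got <- select_window_size(list(W50 = list(values = flat),
                                 W100 = list(values = sep)), labels)
  expect_equal(as.character(got), "W100")
  # exact ties resolve to the earlier (smaller-W) candidate
  tie <- select_window_size(list(W50 = list(values = sep),
                                 W100 = list(values = sep)), labels)
  expect_equal(as.character(tie), "W50")
  one <- select_window_size(list(W150 = list(values = sep)), labels)
  expect_equal(as.character(one), "W150")
})
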