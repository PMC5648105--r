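spec_small <- function(...) synthetic_spec(n_per_group = 3, n_trials = 4,
                                           seed = 42, ...)

test_that("generation is deterministic under fixed seeds", {
  ep1 <- generate_subject(spec_small(), "healthy", 101L)
  ep2 <- generate_subject(spec_small(), "healthy", 101L)
  expect_identical(ep1$data, ep2$data)
  ep3 <- generate_subject(spec_small(), "healthy", 102L)
  expect_false(identical(ep1$data, ep3$data))
  g1 <- generate_cohort(spec_small())
  g2 <- generate_cohort(spec_small())
  expect_identical(g1$cohort$subjects[[5]]$epochs$data,
                   g2$cohort$subjects[[5]]$epochs$data)
})

test_that("spec validation rejects bad gains, lags and artifact rates", {
  expect_error(synthetic_spec(couplings = list(list(
    source = "P8", target = "F2", lag_ms = 20,
    gain_healthy = 1.2, gain_patient = 0.3))), "gains")
  expect_error(synthetic_spec(couplings = list(list(
    source = "P8", target = "F2", lag_ms = 1500,
    gain_healthy = 0.5, gain_patient = 0.5))), "lag")
  expect_error(synthetic_spec(artifact_rate = 1.5), "artifact_rate")
  expect_error(synthetic_spec(couplings = list(list(
    source = "XX", target = "F2", lag_ms = 20,
    gain_healthy = 0.5, gain_patient = 0.5))), "unknown electrode")
})

test_that("gain-1 noise-borne coupling gives correlation 1 at the planted lag", {
  spec <- synthetic_spec(n_per_group = 2, n_trials = 1, seed = 7,
                         erp = c(latency_ms = 300, width_ms = 80,
                                 amplitude_uv = 0),
                         artifact_rate = 0,
                         couplings = list(list(source = "P8", target = "F2",
                                               lag_ms = 20,
                                               gain_healthy = 1,
                                               gain_patient = 1)))
  ep <- generate_subject(spec, "healthy", 11L)
  src <- ep$data[1, 4, ]; tgt <- ep$data[1, 8, ]
  lag <- round(20 * 512 / 1000)
  n <- length(src)
  expect_equal(cor(src[1:(n - lag)], tgt[(lag + 1):n]), 1.0,
               tolerance = 1e-12)
})

test_that("planted lag is recoverable from the mean cross-correlation", {
  spec <- synthetic_spec(n_per_group = 2, n_trials = 8, seed = 3,
                         erp = c(latency_ms = 300, width_ms = 80,
                                 amplitude_uv = 0),
                         artifact_rate = 0,
                         couplings = list(list(source = "P8", target = "F2",
                                               lag_ms = 20,
                                               gain_healthy = 0.8,
                                               gain_patient = 0.3)))
  ep <- generate_subject(spec, "healthy", 21L)
  avg <- aggregate_trials(ep)
  lags <- -15:15
  rs <- vapply(lags, function(phi) {
    n <- ncol(avg)
    i <- max(1, 1 - phi):min(n, n - phi)
    cor(avg[4, i], avg[8, i + phi])
  }, numeric(1))
  expect_equal(lags[which.max(rs)], round(20 * 512 / 1000))
})

test_that("cohorts are balanced and artifact counts follow the rate", {
  gen <- generate_cohort(synthetic_spec(n_per_group = 20, n_trials = 20,
                                        n_channels = 4, fs = 128,
                                        epoch_ms = 500,
                                        couplings = list(),
                                        artifact_rate = 0.1, seed = 9))
  expect_equal(sum(gen$cohort$labels == "healthy"), 20)
  expect_equal(sum(gen$cohort$labels == "patient"), 20)
  counts <- lengths(gen$ground_truth$artifact_trials)
  # binomial(20, 0.1) mean 2 per subject; 40 subjects
  expect_gt(mean(counts), 1.2)
  expect_lt(mean(counts), 2.8)
  # ground truth survives JSON round-trip
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(gen$ground_truth, path, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$labels, gen$ground_truth$labels)
  expect_equal(back$subject_seeds, gen$ground_truth$subject_seeds)
})

test_that("group-mean lagged correlation rises with the planted gain", {
  # executable analogue of connectivity-strength degradation: the planted
  # entry of the group-mean map is monotone in the coupling gain
  spec0 <- synthetic_spec(n_per_group = 4, n_trials = 6, seed = 31)
  cfg <- run_config(window_sizes_ms = 150)
  gains <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  vals <- vapply(gains, function(g) {
    spec <- synthetic_spec(n_per_group = 4, n_trials = 6, seed = 31,
                           couplings = list(list(source = "P8",
                                                 target = "F2", lag_ms = 20,
                                                 gain_healthy = g,
                                                 gain_patient = g)))
    gen <- generate_cohort(spec)
    prep <- prepare_cohort(gen$cohort, cfg)
    mean(prep$tensors[[1]]$values["P8", "F2", ])
  }, numeric(1))
  expect_gte(cor(gains, vals, method = "spearman"), 0.9)
})

test_that("relative-only scenario hides the split from single edges", {
  spec <- synthetic_spec(n_per_group = 6, n_trials = 6, seed = 17)
  gen <- generate_relative_only_scenario(spec)
  lab <- gen$cohort$labels
  expect_equal(sum(lab == "healthy"), 6)
  gt <- gen$ground_truth
  expect_equal(gt$electrodes$C, "O1")
  expect_length(gt$erp_scales, 12)
  # swapped-gain construction: REL group-mean difference flips sign when
  # classes are exchanged (by symmetry of the generator)
  prep <- prepare_cohort(gen$cohort, run_config(window_sizes_ms = 200))
  tn <- prep$tensors[[1]]
  rel <- tn$values["O1", "F1", ] - tn$values["O1", "F2", ]
  d <- mean(rel[lab == "healthy"]) - mean(rel[lab == "patient"])
  expect_gt(abs(d), 0.05)
  # swapping which target the class favors flips the sign of the
  # group-mean REL difference
  gen2 <- generate_relative_only_scenario(spec,
                                          electrodes = list(C = "O1",
                                                            A = "F2",
                                                            B = "F1"))
  prep2 <- prepare_cohort(gen2$cohort, run_config(window_sizes_ms = 200))
  rel2 <- prep2$tensors[[1]]$values["O1", "F1", ] -
    prep2$tensors[[1]]$values["O1", "F2", ]
  d2 <- mean(rel2[lab == "healthy"]) - mean(rel2[lab == "patient"])
  expect_lt(d * d2, 0)
  # direct A-B difference is an order of magnitude below the REL difference
  ab <- tn$values["F1", "F2", ]
  d_ab <- mean(ab[lab == "healthy"]) - mean(ab[lab == "patient"])
  expect_gt(abs(d) / max(abs(d_ab), 1e-9), 5)
})
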