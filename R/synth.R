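#' Synthetic two-group ERP cohort specification
#'
#' Describes a cohort of epoched EEG emulating a stimulus-locked recording:
#' per-channel 1/f background noise, a shared evoked component (Gaussian-
#' windowed half-sine), planted lagged couplings whose gain differs between
#' the two classes, and occasional high-amplitude artifact trials that
#' exercise the 75 uV rejection path.
#'
#' Every channel carries its own evoked bump: the shared latency is offset
#' per channel by `erp_gradient_ms * y` (scalp front-back coordinate), a
#' crude posterior-to-frontal latency gradient, plus a per-subject latency
#' jitter -- so evoked waveforms differ across the scalp and cannot be
#' realigned within the small lag limit of the connectivity scan.
#'
#' A coupling `list(source=, target=, lag_ms=, gain_healthy=, gain_patient=)`
#' mixes the source's full signal (evoked + noise) into the target:
#' `target = g * delayed(source, lag) + sqrt(1 - g^2) * own`, with `own`
#' the target's private evoked-plus-noise signal.  The mix is variance
#' preserving, so in the evoked-free limit the planted lagged correlation
#' is ~ `g`, and with an evoked component the *trial-averaged* waveforms
#' (what the connectivity statistic actually correlates) inherit the group
#' contrast: at high gain the target's average is dominated by the
#' delayed source waveform, at low gain by its own differently-timed bump.
#' The default plants a posterior-to-frontal coupling (P8 to F2, 20 ms
#' lag) with gain 0.8 in the healthy class and 0.3 in the patient class,
#' mirroring reduced long-range posterior-frontal coupling in patients.
#'
#' @param n_per_group subjects per class.
#' @param n_channels electrode count; 8 uses [demo_montage()], other values
#'   a generic circular montage (couplings must then name its electrodes).
#' @param fs sampling rate (Hz).
#' @param t0_ms epoch start relative to stimulus (ms).
#' @param epoch_ms epoch duration (ms).
#' @param n_trials trials (stimulus repetitions) per subject.
#' @param couplings list of coupling specs (see Details); `list()` for a
#'   pure-noise (label-exchangeable) cohort.
#' @param erp named vector `c(latency_ms=, width_ms=, amplitude_uv=)`.
#' @param erp_gradient_ms scalp latency gradient: channel latency offset is
#'   this value times `y + 0.6 x` of the montage position, a diagonal
#'   gradient giving every electrode a distinct evoked latency (0 disables).
#' @param erp_jitter_ms half-range of the per-subject latency jitter.
#' @param noise named vector `c(exponent=, amplitude_uv=)`; power ~ 1/f^exp.
#' @param artifact_rate fraction of trials given a 100 uV, 50 ms square
#'   pulse on one random channel.
#' @param seed master seed; per-subject seeds are derived by counter so a
#'   cohort can be extended without reshuffling existing subjects.
#' @param montage optional explicit [montage()].
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_group = 20, n_channels = 8, fs = 512,
                           t0_ms = -200, epoch_ms = 1200, n_trials = 15,
                           couplings = list(list(source = "P8",
                                                 target = "F2",
                                                 lag_ms = 20,
                                                 gain_healthy = 0.8,
                                                 gain_patient = 0.3)),
                           erp = c(latency_ms = 300, width_ms = 40,
                                   amplitude_uv = 12),
                           erp_gradient_ms = 70, erp_jitter_ms = 10,
                           noise = c(exponent = 1, amplitude_uv = 3),
                           artifact_rate = 0.05,
                           seed = 1L, montage = NULL) {
  if (is.null(montage))
    montage <- if (n_channels == 8) demo_montage() else circle_montage(n_channels)
  stopifnot(length(montage$names) == n_channels)
  for (cp in couplings) {
    g <- c(cp$gain_healthy, cp$gain_patient)
    if (any(g < 0 | g > 1)) stop("coupling gains must lie in [0, 1]")
    if (cp$lag_ms >= epoch_ms) stop("coupling lag exceeds the epoch")
    if (!all(c(cp$source, cp$target) %in% montage$names))
      stop("coupling names unknown electrode(s)")
  }
  if (artifact_rate < 0 || artifact_rate > 1)
    stop("artifact_rate must be in [0, 1]")
  structure(list(n_per_group = as.integer(n_per_group),
                 n_channels = as.integer(n_channels), fs = fs,
                 t0_ms = t0_ms, epoch_ms = epoch_ms,
                 n_trials = as.integer(n_trials), couplings = couplings,
                 erp = erp, erp_gradient_ms = erp_gradient_ms,
                 erp_jitter_ms = erp_jitter_ms,
                 noise = noise, artifact_rate = artifact_rate,
                 seed = as.integer(seed), montage = montage),
            class = "synthetic_spec")
}

# deterministic per-subject seed: the i-th draw of the master seed's own
# RNG stream.  Prefix-stable (growing the cohort never reshuffles existing
# subjects) and, unlike arithmetic counter schemes, free of the
# index-linked correlations that linearly related seeds induce in the
# generator state -- those made early-index subjects resemble each other
# and broke label exchangeability of null cohorts.
subject_seed <- function(master, i) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(as.numeric(master) %% 2147483647))
  u <- stats::runif(i)
  as.integer(floor(u[i] * 2147483645)) + 1L
}

# 1/f^exponent-shaped Gaussian noise, unit sd, length S
pink_noise <- function(S, exponent) {
  w <- stats::rnorm(S)
  if (exponent == 0) return(w)
  W <- stats::fft(w)
  f <- c(1, seq_len(S - 1))                       # DC kept at weight of f=1
  f <- pmin(f, S - f + 1)                         # fold about Nyquist
  amp <- f^(-exponent / 2)
  x <- Re(stats::fft(W * amp, inverse = TRUE)) / S
  as.numeric(x / stats::sd(x))
}

# Gaussian-windowed half-sine evoked bump, peak `amplitude` at `latency_ms`
erp_bump <- function(S, fs, t0_ms, latency_ms, width_ms, amplitude_uv) {
  t <- t0_ms + (seq_len(S) - 1) / fs * 1000
  u <- (t - latency_ms) / width_ms
  win <- exp(-u^2 / 2)
  half <- sin(pi / 2 * pmax(-1, pmin(1, u + 1)))  # rises into the peak
  amplitude_uv * win * half
}

delay_samples <- function(x, lag) {
  if (lag == 0) return(x)
  c(rep(0, lag), x[seq_len(length(x) - lag)])
}

#' Generate one synthetic subject
#'
#' Deterministic given `(spec$seed, subj_seed)`.  Trials planted with an
#' artifact pulse are recorded in the `artifact_trials` attribute of the
#' returned [epoch_set()].
#'
#' @param spec a [synthetic_spec()].
#' @param label `"healthy"` or `"patient"` (selects the coupling gain).
#' @param subj_seed integer seed for this subject.
#' @param couplings optional per-subject coupling override (used by
#'   [generate_relative_only_scenario()]).
#' @param erp_scale optional per-channel multiplier on the evoked
#'   amplitude (length `n_channels`); models between-subject ERP
#'   amplitude variability.
#' @return An [epoch_set()].
#' @export
generate_subject <- function(spec, label, subj_seed,
                             couplings = spec$couplings,
                             erp_scale = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"),
            label %in% c("healthy", "patient"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(subj_seed)
  S <- epoch_n_samples(spec$fs, spec$epoch_ms)
  n <- spec$n_channels
  # per-subject latency jitter (a subject trait, shared across trials and
  # channels) on top of the fixed scalp latency gradient
  jitter <- stats::runif(1, -spec$erp_jitter_ms, spec$erp_jitter_ms)
  # diagonal scalp gradient: every electrode gets a distinct evoked
  # latency, so no channel is a waveform proxy for another
  lat <- spec$erp[["latency_ms"]] + jitter +
    spec$erp_gradient_ms * (spec$montage$positions[, "y"] +
                              0.6 * spec$montage$positions[, "x"])
  if (is.null(erp_scale)) erp_scale <- rep(1, n)
  stopifnot(length(erp_scale) == n)
  bumps <- vapply(seq_len(n), function(c)
    erp_bump(S, spec$fs, spec$t0_ms, lat[c], spec$erp[["width_ms"]],
             erp_scale[c] * spec$erp[["amplitude_uv"]]), numeric(S))  # S x n
  gkey <- if (label == "healthy") "gain_healthy" else "gain_patient"
  arr <- array(0, dim = c(spec$n_trials, n, S))
  art_dur <- max(1L, as.integer(round(0.05 * spec$fs)))
  artifact_trials <- integer(0)
  for (tr in seq_len(spec$n_trials)) {
    own <- matrix(0, n, S)
    for (c in seq_len(n))
      own[c, ] <- pink_noise(S, spec$noise[["exponent"]]) *
        spec$noise[["amplitude_uv"]] + bumps[, c]
    X <- own
    for (cp in couplings) {
      si <- match(cp$source, spec$montage$names)
      ti <- match(cp$target, spec$montage$names)
      g <- cp[[gkey]]
      lag <- as.integer(round(cp$lag_ms * spec$fs / 1000))
      X[ti, ] <- g * delay_samples(own[si, ], lag) +
        sqrt(1 - g^2) * own[ti, ]
    }
    if (stats::runif(1) < spec$artifact_rate) {
      ch <- sample.int(n, 1)
      onset <- sample.int(S - art_dur, 1)
      X[ch, onset:(onset + art_dur - 1L)] <- X[ch, onset:(onset + art_dur - 1L)] + 100
      artifact_trials <- c(artifact_trials, tr)
    }
    arr[tr, , ] <- X
  }
  ep <- epoch_set(arr, spec$fs, spec$t0_ms)
  attr(ep, "artifact_trials") <- artifact_trials
  ep
}

#' Generate a balanced two-group cohort
#'
#' @param spec a [synthetic_spec()] with `n_per_group >= 2`.
#' @return list with `cohort` (a [cohort_dataset()]) and `ground_truth`
#'   (planted couplings, per-class gains, subject seeds, artifact trials).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_per_group < 2) stop("need at least 2 subjects per group")
  N <- 2L * spec$n_per_group
  labels <- rep(c("healthy", "patient"), each = spec$n_per_group)
  seeds <- vapply(seq_len(N), function(i) subject_seed(spec$seed, i), 0L)
  art <- vector("list", N)
  subjects <- lapply(seq_len(N), function(i) {
    ep <- generate_subject(spec, labels[i], seeds[i])
    art[[i]] <<- attr(ep, "artifact_trials")
    list(id = sprintf("sub%02d", i), epochs = ep, label = labels[i])
  })
  names(art) <- sprintf("sub%02d", seq_len(N))
  gt <- list(couplings = spec$couplings, labels = labels,
             subject_seeds = seeds, artifact_trials = art)
  list(cohort = cohort_dataset(subjects, spec$montage), ground_truth = gt)
}

#' Cohort whose group difference is visible only through relative features
#'
#' A reference electrode C drives two target electrodes A and B with a
#' class-swapped gain split (`0.5 + delta` on the favored target,
#' `0.5 - delta` on the other; healthy favor A, patients favor B).  On
#' top of that, every subject carries a private evoked-amplitude scale
#' `s_i ~ U(0.1, 5)` on the two target channels (between-subject ERP
#' amplitude variability), a nuisance that moves every direct correlation
#' involving A or B much more than the gain split does -- so per-edge
#' (direct) features are diluted, while
#' `REL_C(A,B) = conn_C(A) - conn_C(B)` compares the two edges *within* a
#' subject at the same nuisance and isolates the split.  Direct A-B
#' connectivity (induced by the shared drive, a product of the two
#' loadings) is class-symmetric by construction.  Default electrodes:
#' C = O1 (posterior reference), A = F1, B = F2 (frontal targets), with
#' the scenario's own latency gradient (50 ms per scalp unit) keeping the
#' correlation sensitive to the gain split.  Note that REL columns are
#' linear in direct connectivity values, so a direct-only pipeline
#' retains part of the split through the joint distribution of the two
#' edges; the vignette quantifies how far this caps the contrast.
#'
#' @param spec a [synthetic_spec()]; its `couplings` are ignored.
#' @param electrodes named list with entries `C`, `A`, `B`.
#' @param delta half-gap of the class-swapped gain split.
#' @param base_range range of the per-subject common coupling strength
#'   added to both edges (an additive nuisance REL cancels exactly;
#'   degenerate by default).
#' @param scale_range range of the per-subject target-ERP amplitude scale
#'   (a multiplicative nuisance).
#' @param gradient_ms the scenario's evoked latency gradient (overrides
#'   the spec's).
#' @return As [generate_cohort()]; `ground_truth` records C/A/B, the gain
#'   split and the per-subject nuisances.
#' @export
generate_relative_only_scenario <- function(spec,
                                            electrodes = list(C = "O1",
                                                              A = "F1",
                                                              B = "F2"),
                                            delta = 0.2,
                                            base_range = c(0.5, 0.5),
                                            scale_range = c(0.1, 5),
                                            gradient_ms = 50) {
  stopifnot(inherits(spec, "synthetic_spec"))
  stopifnot(all(unlist(electrodes) %in% spec$montage$names))
  # this scenario's documented latency geometry: the O1->F1/F2 separation
  # that keeps the correlation sensitive to the gain split
  spec$erp_gradient_ms <- gradient_ms
  N <- 2L * spec$n_per_group
  labels <- rep(c("healthy", "patient"), each = spec$n_per_group)
  seeds <- vapply(seq_len(N), function(i) subject_seed(spec$seed, i), 0L)
  # nuisance draws use a separate derived master stream
  nuis_seeds <- vapply(seq_len(N),
                       function(i) subject_seed(spec$seed + 500009L, i), 0L)
  ai <- match(electrodes$A, spec$montage$names)
  bi <- match(electrodes$B, spec$montage$names)
  scales <- numeric(N); bases <- numeric(N)
  subjects <- lapply(seq_len(N), function(i) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(nuis_seeds[i])
    s_i <- stats::runif(1, scale_range[1], scale_range[2])
    b_i <- stats::runif(1, base_range[1], base_range[2])
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    scales[i] <<- s_i; bases[i] <<- b_i
    up <- min(1, b_i + delta); dn <- max(0, b_i - delta)
    cps <- list(
      list(source = electrodes$C, target = electrodes$A, lag_ms = 20,
           gain_healthy = up, gain_patient = dn),
      list(source = electrodes$C, target = electrodes$B, lag_ms = 20,
           gain_healthy = dn, gain_patient = up))
    esc <- rep(1, spec$n_channels)
    esc[c(ai, bi)] <- s_i
    ep <- generate_subject(spec, labels[i], seeds[i], couplings = cps,
                           erp_scale = esc)
    list(id = sprintf("sub%02d", i), epochs = ep, label = labels[i])
  })
  gt <- list(electrodes = electrodes, delta = delta, bases = bases,
             erp_scales = scales, labels = labels, subject_seeds = seeds)
  list(cohort = cohort_dataset(subjects, spec$montage), ground_truth = gt)
}
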