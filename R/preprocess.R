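## Preprocessing: zero-phase filtering, band decomposition, amplitude
## rejection, std normalization, trial aggregation and the sliding-window
## grid.

# Zero-phase Butterworth-magnitude band filter, applied spectrally: each
# epoch is multiplied in the frequency domain by the squared Butterworth
# magnitude |H_lp(f)|^2 * |H_hp(f)|^2.  Exactly zero phase (lags carry
# the connectivity signal, so phase distortion is not acceptable), free
# of the start/end transients that forward-backward IIR filtering leaves
# on ~1 s epochs, and power-complementary by construction: a same-order
# low/high pair at a shared cutoff sums exactly to one, so summing the
# six sub-band signals reconstructs the broadband signal.  Edges use
# order 8 (a 40 Hz tone keeps < 2% RMS after 0.1-30 Hz filtering); the
# near-DC floor (< 1 Hz) uses a gentle order 2.
.band_response <- function(n, fs, low, high) {
  nyq <- fs / 2
  if (low >= high) stop("band edges must satisfy low < high, got [",
                        low, ", ", high, "]")
  if (high > nyq) stop("band [", low, ", ", high,
                       "] exceeds the Nyquist frequency ", nyq)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  resp <- 1 / (1 + (f / high)^16)            # |H_lp|^2, order 8
  if (low > 0) {
    hp_ord <- if (low < 1) 2 else 8
    hp <- ifelse(f == 0, 0, 1 / (1 + (low / f)^(2 * hp_ord)))
    resp <- resp * hp
  }
  resp
}

# filter the columns of a samples x m matrix in one FFT pass
.apply_response <- function(mat, resp) {
  Re(stats::mvfft(stats::mvfft(mat) * resp, inverse = TRUE)) / nrow(mat)
}

#' Zero-phase band-pass filter an epoch set
#'
#' Spectral zero-phase Butterworth-magnitude filtering per trial and
#' channel (see the package vignette for the design rationale); DC is
#' removed whenever `low > 0`.
#'
#' @param epochs an [epoch_set()].
#' @param low,high band edges in Hz; `high` must not exceed Nyquist.
#' @return A filtered copy of `epochs`.
#' @export
bandpass <- function(epochs, low, high) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- epochs$data
  dm <- dim(d)
  resp <- .band_response(dm[3], epochs$fs, low, high)
  mat <- matrix(aperm(d, c(3, 1, 2)), nrow = dm[3])
  filt <- .apply_response(mat, resp)
  out <- epochs
  out$data <- aperm(array(filt, dim = c(dm[3], dm[1], dm[2])), c(2, 3, 1))
  out
}

#' Filter an epoch set to a (possibly multi-interval) band specification
#'
#' A band subset is reconstructed as the sum of its member intervals'
#' zero-phase filtered signals.
#'
#' @param epochs an [epoch_set()].
#' @param band a band spec: list with `name` and `intervals` (rows of
#'   (low, high) Hz), as produced by [enumerate_band_subsets()].
#' @return A filtered copy of `epochs`.
#' @export
band_filter <- function(epochs, band) {
  iv <- band$intervals
  if (is.null(dim(iv))) iv <- matrix(iv, ncol = 2)
  out <- bandpass(epochs, iv[1, 1], iv[1, 2])
  if (nrow(iv) > 1) {
    for (k in 2:nrow(iv)) {
      add <- bandpass(epochs, iv[k, 1], iv[k, 2])
      out$data <- out$data + add$data
    }
  }
  out
}

#' Enumerate sub-band combinations of the analysis band
#'
#' Splits `[full_low, full_high]` into six equal-width intervals (the first
#' starting at the filter floor `full_low`), forms all 63 non-empty subsets
#' of the six, and appends the classical named bands (delta, theta, alpha,
#' beta; gamma only when the band reaches past 30 Hz).
#'
#' @param full_low,full_high broadband edges in Hz (default 0.1-30).
#' @return list of band specs `list(name=, intervals=)`; the first six are
#'   the single intervals, the 63rd subset is the full band.
#' @export
enumerate_band_subsets <- function(full_low = 0.1, full_high = 30) {
  step <- full_high / 6
  edges_lo <- c(full_low, step * (1:5))
  edges_hi <- step * (1:6)
  iname <- sprintf("%g-%gHz", edges_lo, edges_hi)
  subsets <- list()
  for (k in 1:63) {
    members <- which(bitwAnd(k, bitwShiftL(1L, 0:5)) != 0L)
    subsets[[length(subsets) + 1L]] <- list(
      name = paste(iname[members], collapse = "+"),
      intervals = cbind(edges_lo[members], edges_hi[members]))
  }
  classical <- list(
    list(name = "delta", intervals = cbind(full_low, 4)),
    list(name = "theta", intervals = cbind(4, 8)),
    list(name = "alpha", intervals = cbind(8, 13)),
    list(name = "beta",  intervals = cbind(13, 30)))
  if (full_high > 30)
    classical <- c(classical,
                   list(list(name = "gamma", intervals = cbind(30, full_high))))
  c(subsets, classical)
}

#' Mark trials exceeding an absolute amplitude threshold as invalid
#'
#' Evaluated on filtered, pre-normalization microvolt values (normalizing
#' first would destroy the physical meaning of the threshold).  A trial is
#' valid when its maximum absolute amplitude over all channels and samples
#' is at or below the threshold AND the external mask (behavioral misses,
#' ocular exclusions produced outside this package) allows it.  Idempotent.
#'
#' @param epochs an [epoch_set()].
#' @param threshold_uv rejection threshold in microvolts (default 75).
#' @param external_mask optional logical per-trial mask (TRUE = keep).
#' @return `epochs` with `trial_valid` updated; the number of amplitude
#'   rejections is stored in the `n_rejected` attribute.
#' @export
reject_epochs <- function(epochs, threshold_uv = 75, external_mask = NULL) {
  stopifnot(inherits(epochs, "epoch_set"), threshold_uv > 0)
  nt <- n_trials(epochs)
  if (is.null(external_mask)) external_mask <- rep(TRUE, nt)
  stopifnot(length(external_mask) == nt)
  amp_ok <- vapply(seq_len(nt),
                   function(tr) max(abs(epochs$data[tr, , ])) <= threshold_uv,
                   logical(1))
  out <- epochs
  out$trial_valid <- amp_ok & external_mask
  attr(out, "n_rejected") <- sum(!amp_ok)
  out
}

#' Normalize each channel by its standard deviation
#'
#' The std is computed per channel over all samples of all *valid* trials;
#' afterwards each channel has unit std over that segment.  Channels with
#' zero variance are left unscaled and flagged for exclusion from
#' connectivity.
#'
#' @param epochs an [epoch_set()].
#' @return Normalized copy; attributes `channel_std` and
#'   `excluded_channels` (indices of zero-variance channels, if any).
#' @export
normalize_std <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- epochs$trial_valid
  if (!any(keep)) stop("no valid trials to compute channel std",
                       if (!is.null(epochs$subject_id))
                         paste0(" for subject '", epochs$subject_id, "'"))
  nc <- n_channels(epochs)
  sds <- vapply(seq_len(nc), function(ch) {
    v <- as.numeric(epochs$data[keep, ch, ])
    sqrt(mean((v - mean(v))^2))
  }, numeric(1))
  excluded <- which(sds == 0)
  out <- epochs
  for (ch in seq_len(nc))
    if (sds[ch] > 0) out$data[, ch, ] <- out$data[, ch, ] / sds[ch]
  attr(out, "channel_std") <- sds
  attr(out, "excluded_channels") <- excluded
  out
}

#' Aggregate trials into one channels x samples array
#'
#' Elementwise mean (default), median or max over the first `n_stimuli`
#' *valid* trials; invalid trials are skipped, not counted.
#'
#' @param epochs an [epoch_set()].
#' @param mode `"mean"`, `"median"` or `"max"`.
#' @param n_stimuli trials used from the recording start (NULL = all valid).
#' @param min_valid fewer used trials than this raises a warning; zero is
#'   an error naming the subject.
#' @return channels x samples numeric matrix; attribute `n_used` records
#'   the number of aggregated trials.
#' @export
aggregate_trials <- function(epochs, mode = c("mean", "median", "max"),
                             n_stimuli = NULL, min_valid = 3L) {
  stopifnot(inherits(epochs, "epoch_set"))
  mode <- match.arg(mode)
  valid <- which(epochs$trial_valid)
  if (!length(valid))
    stop("no usable trials",
         if (!is.null(epochs$subject_id))
           paste0(" for subject '", epochs$subject_id, "'"))
  if (!is.null(n_stimuli)) valid <- utils::head(valid, n_stimuli)
  if (length(valid) < min_valid)
    warning("only ", length(valid), " valid trial(s) aggregated",
            if (!is.null(epochs$subject_id))
              paste0(" for subject '", epochs$subject_id, "'"))
  d <- epochs$data[valid, , , drop = FALSE]
  out <- switch(mode,
                mean = apply(d, c(2, 3), mean),
                median = apply(d, c(2, 3), stats::median),
                max = apply(d, c(2, 3), max))
  attr(out, "n_used") <- length(valid)
  out
}

#' Sliding-window grid over the analysis interval
#'
#' Windows of size W start at the interval start and advance by
#' `W * (1 - overlap)` rounded down to whole samples (never below one
#' sample); every window `[start, start + W)` lies inside
#' `[interval_start, interval_end)`.
#'
#' @param fs sampling rate (Hz).
#' @param t0_ms epoch start relative to stimulus (ms).
#' @param n_samp samples per epoch.
#' @param window_ms window size W in ms.
#' @param interval_ms analysis interval `[start, end)` in ms post-stimulus.
#' @param overlap overlap fraction in `[0, 1)` (default 0.9).
#' @return list of class `window_grid`: `w_samp`, `step_samp`, `starts`
#'   (1-based sample indices), `starts_ms`, `window_ms`.
#' @export
make_window_grid <- function(fs, t0_ms, n_samp, window_ms,
                             interval_ms = c(200, 450), overlap = 0.9) {
  w <- as.integer(round(window_ms * fs / 1000))
  if (w < 2) stop("window of ", window_ms, " ms is below 2 samples at ",
                  fs, " Hz")
  i0 <- ms_to_sample(interval_ms[1], fs, t0_ms)
  i1 <- ms_to_sample(interval_ms[2], fs, t0_ms)   # exclusive
  i0 <- max(i0, 1L)
  i1 <- min(i1, n_samp + 1L)
  last <- i1 - w
  if (last < i0)
    stop("no window of ", window_ms, " ms fits in the interval [",
         interval_ms[1], ", ", interval_ms[2], ") ms")
  step <- max(1L, as.integer(floor(w * (1 - overlap) + 1e-9)))
  starts <- seq.int(i0, last, by = step)
  structure(list(window_ms = window_ms, w_samp = w, step_samp = step,
                 starts = starts,
                 starts_ms = t0_ms + (starts - 1) / fs * 1000),
            class = "window_grid")
}
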