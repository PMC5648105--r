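#' Epoched recording of one subject
#'
#' Holds a trials x channels x samples array of stimulus-locked EEG in
#' microvolts, the sampling rate, and the epoch start relative to stimulus
#' onset.  Sample index 1 corresponds to `t0_ms` (negative = pre-stimulus);
#' all window conventions downstream are half-open in time.
#'
#' @param data numeric 3-d array, trials x channels x samples (microvolts).
#' @param fs sampling rate in Hz (> 0).
#' @param t0_ms epoch start relative to stimulus onset, in ms.
#' @param trial_valid logical mask per trial; defaults to all-true.
#' @param subject_id optional identifier used in error messages.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, t0_ms, trial_valid = NULL,
                      subject_id = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("epoch data must be a trials x channels x samples array")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar")
  if (is.null(trial_valid)) trial_valid <- rep(TRUE, dim(data)[1L])
  if (length(trial_valid) != dim(data)[1L])
    stop("trial_valid length must equal the number of trials")
  structure(list(data = data, fs = as.numeric(fs), t0_ms = as.numeric(t0_ms),
                 trial_valid = as.logical(trial_valid),
                 subject_id = subject_id),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials (%d valid) x %d channels x %d samples @ %g Hz, t0 = %g ms\n",
              d[1], sum(x$trial_valid), d[2], d[3], x$fs, x$t0_ms))
  invisible(x)
}

n_trials   <- function(ep) dim(ep$data)[1L]
n_channels <- function(ep) dim(ep$data)[2L]
n_samples  <- function(ep) dim(ep$data)[3L]

# number of samples in an epoch of `epoch_ms` at rate fs: 1.2 s at 512 Hz
# gives round(614.4) = 614, applied uniformly
epoch_n_samples <- function(fs, epoch_ms) as.integer(round(epoch_ms * fs / 1000))

# sample index (1-based) of a time point in ms relative to stimulus
ms_to_sample <- function(t_ms, fs, t0_ms) {
  as.integer(round((t_ms - t0_ms) * fs / 1000)) + 1L
}

#' Multi-subject labeled cohort
#'
#' @param subjects list of entries `list(id=, epochs=, label=)`, with
#'   `epochs` an [epoch_set()] and `label` one of `"healthy"`, `"patient"`.
#' @param montage an [montage()]; channel order of every subject must match.
#' @return An object of class `cohort_dataset` with elements `subjects`,
#'   `labels` (factor healthy/patient) and `montage`.
#' @export
cohort_dataset <- function(subjects, montage) {
  stopifnot(inherits(montage, "eeg_montage"))
  if (length(subjects) < 2L) stop("a cohort needs at least 2 subjects")
  labs <- vapply(subjects, function(s) s$label, character(1))
  if (!all(labs %in% c("healthy", "patient")))
    stop("labels must be 'healthy' or 'patient'")
  n <- length(montage$names)
  fs <- vapply(subjects, function(s) s$epochs$fs, numeric(1))
  t0 <- vapply(subjects, function(s) s$epochs$t0_ms, numeric(1))
  nch <- vapply(subjects, function(s) n_channels(s$epochs), integer(1))
  ns <- vapply(subjects, function(s) n_samples(s$epochs), integer(1))
  if (length(unique(fs)) != 1L || length(unique(t0)) != 1L ||
      length(unique(ns)) != 1L)
    stop("all subjects must share fs, t0_ms and epoch length")
  bad <- which(nch != n)
  if (length(bad))
    stop("channel count of subject '", subjects[[bad[1]]]$id,
         "' (", nch[bad[1]], ") does not match the montage (", n, ")")
  ids <- vapply(subjects, function(s) as.character(s$id), character(1))
  if (anyDuplicated(ids)) stop("subject ids must be unique")
  structure(list(subjects = subjects,
                 labels = factor(labs, levels = c("healthy", "patient")),
                 montage = montage),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d subjects (%d healthy / %d patient), %d channels @ %g Hz\n",
              length(x$subjects), sum(x$labels == "healthy"),
              sum(x$labels == "patient"), length(x$montage$names),
              x$subjects[[1]]$epochs$fs))
  invisible(x)
}

cohort_ids <- function(cd) vapply(cd$subjects, function(s) as.character(s$id),
                                  character(1))
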