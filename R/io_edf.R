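## Minimal EDF/BDF continuous-recording I/O.
##
## EDF stores a 256-byte fixed-layout ASCII header, 256 bytes per signal of
## per-signal header fields, then data records of little-endian 16-bit
## integers (24-bit for BDF) scaled linearly between digital and physical
## ranges.  Only what the epoching pipeline needs is implemented: uniform
## sampling rate across kept channels and physical units taken as given
## (microvolts for EEG channels).

.read_ascii <- function(con, nchar) trimws(rawToChar(readBin(con, "raw", nchar)))

#' Read a continuous EDF or BDF recording
#'
#' @param path an `.edf` (16-bit) or `.bdf` (24-bit, Biosemi) file.
#' @return list with `data` (channels x samples matrix, physical units),
#'   `fs`, `labels` (channel labels), `n_records`, `record_duration_s`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("recording not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  bdf <- magic[1] == as.raw(255)
  # patient, recording, date, time
  invisible(readBin(con, "raw", 80 + 80 + 8 + 8))
  invisible(.read_ascii(con, 8))            # header length
  invisible(.read_ascii(con, 44))           # reserved
  n_rec <- as.integer(.read_ascii(con, 8))
  dur <- as.numeric(.read_ascii(con, 8))
  ns <- as.integer(.read_ascii(con, 4))
  labels <- vapply(seq_len(ns), function(i) .read_ascii(con, 16), character(1))
  invisible(readBin(con, "raw", ns * 80))   # transducer
  invisible(readBin(con, "raw", ns * 8))    # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(.read_ascii(con, 8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(.read_ascii(con, 8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(.read_ascii(con, 8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(.read_ascii(con, 8)), 0)
  invisible(readBin(con, "raw", ns * 80))   # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(.read_ascii(con, 8)), 0L)
  invisible(readBin(con, "raw", ns * 32))   # reserved
  if (length(unique(spr)) != 1L)
    stop("channels with differing sampling rates are not supported")
  out <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      if (bdf) {
        raw3 <- readBin(con, "raw", 3L * spr[s])
        b <- matrix(as.integer(raw3), nrow = 3)
        v <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
      } else {
        v <- readBin(con, "integer", spr[s], size = 2, endian = "little")
      }
      gain <- (pmax[s] - pmin[s]) / (dmax[s] - dmin[s])
      out[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
        (v - dmin[s]) * gain + pmin[s]
    }
  }
  rownames(out) <- labels
  list(data = out, fs = spr[1] / dur, labels = labels, n_records = n_rec,
       record_duration_s = dur)
}

#' Write a minimal single-record EDF file
#'
#' Intended for exporting simulated continuous recordings and for
#' round-trip tests; one data record spanning the whole signal, physical
#' range set from the data.
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param labels channel labels (default: rownames of `data`).
#' @param path target `.edf` file.
#' @export
write_edf <- function(data, fs, path, labels = rownames(data)) {
  stopifnot(is.matrix(data), !is.null(labels),
            length(labels) == nrow(data))
  ns <- nrow(data); nsamp <- ncol(data)
  pmax <- max(1, ceiling(max(abs(data))))
  pmin <- -pmax
  dmax <- 32767; dmin <- -32768
  dig <- round((data - pmin) / (pmax - pmin) * (dmax - dmin) + dmin)
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeBin(charToRaw(pad(x, w)), con)
  wr("0", 8); wr("simulated", 80); wr("connmaps", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8); wr("", 44)
  wr("1", 8)                                   # one data record
  wr(format(nsamp / fs, digits = 10), 8)       # record duration (s)
  wr(ns, 4)
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("simulated", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(pmin, 8)
  for (i in seq_len(ns)) wr(pmax, 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("none", 80)
  for (i in seq_len(ns)) wr(nsamp, 8)
  for (i in seq_len(ns)) wr("", 32)
  for (s in seq_len(ns))
    writeBin(as.integer(dig[s, ]), con, size = 2, endian = "little")
  invisible(path)
}

#' Cut stimulus-locked epochs from a continuous recording
#'
#' Epochs span `[t0_ms, t0_ms + epoch_ms)` around each stimulus onset;
#' onsets whose epoch would cross a recording edge are dropped with a
#' warning (not an error).  Channels are restricted to, and reordered by,
#' the montage.
#'
#' @param path EDF/BDF file (see [read_edf()]).
#' @param events data frame with column `onset_sample` (1-based sample
#'   index of stimulus onset).
#' @param montage an [montage()]; every montage electrode must exist in the
#'   recording.
#' @param cfg a [run_config()] supplying `epoch_ms`; its `t0_ms` analogue
#'   is taken from `t0_ms`.
#' @param t0_ms epoch start relative to onset (ms, negative = pre-stimulus).
#' @return An [epoch_set()].
#' @export
read_raw_recording <- function(path, events, montage, cfg = run_config(),
                               t0_ms = -200) {
  rec <- read_edf(path)
  missing_ch <- setdiff(montage$names, rec$labels)
  if (length(missing_ch))
    stop("recording lacks montage channel(s): ",
         paste(missing_ch, collapse = ", "))
  X <- rec$data[match(montage$names, rec$labels), , drop = FALSE]
  S_total <- ncol(X)
  n_samp <- epoch_n_samples(rec$fs, cfg$epoch_ms)
  off <- as.integer(round(t0_ms * rec$fs / 1000))
  onsets <- as.integer(events$onset_sample)
  if (is.null(onsets)) stop("events must contain an 'onset_sample' column")
  first <- onsets + off
  keep <- first >= 1L & (first + n_samp - 1L) <= S_total
  if (any(!keep))
    warning(sum(!keep), " onset(s) too close to the recording edge; dropped")
  first <- first[keep]
  if (!length(first)) stop("no epoch fits inside the recording")
  arr <- array(0, dim = c(length(first), nrow(X), n_samp))
  for (i in seq_along(first))
    arr[i, , ] <- X[, first[i]:(first[i] + n_samp - 1L)]
  epoch_set(arr, rec$fs, t0_ms)
}
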