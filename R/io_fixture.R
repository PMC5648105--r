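#' Write / read an epoch-fixture directory
#'
#' The fixture layout is plain text: `montage.tsv` (see [write_montage()]),
#' `metadata.json` with the shared acquisition parameters and the subject
#' table, and one CSV per subject holding the trials x channels x samples
#' array flattened to (trial-major) rows of samples.
#'
#' @param cohort a [cohort_dataset()].
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_epoch_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_montage(cohort$montage, file.path(dir, "montage.tsv"))
  subs <- lapply(cohort$subjects, function(s) {
    ep <- s$epochs
    fn <- paste0(s$id, ".csv")
    d <- dim(ep$data)
    flat <- matrix(aperm(ep$data, c(3, 2, 1)), nrow = d[1] * d[2],
                   byrow = TRUE)  # rows: (trial 1 ch 1..n), (trial 2 ...)
    utils::write.table(flat, file.path(dir, fn), sep = ",",
                       row.names = FALSE, col.names = FALSE)
    list(id = s$id, label = s$label, file = fn,
         n_trials = d[1], trial_valid = ep$trial_valid)
  })
  ep1 <- cohort$subjects[[1]]$epochs
  meta <- list(fs = ep1$fs, t0_ms = ep1$t0_ms, n_samples = n_samples(ep1),
               n_channels = n_channels(ep1), subjects = subs)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_epoch_fixture
#' @param path fixture directory.
#' @return For `read_epoch_fixture`, a validated [cohort_dataset()] with
#'   channel order matching the montage.
#' @export
read_epoch_fixture <- function(path) {
  meta_file <- file.path(path, "metadata.json")
  if (!dir.exists(path) || !file.exists(meta_file))
    stop("not an epoch fixture: missing metadata.json in '", path, "'")
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  for (f in c("fs", "t0_ms", "n_samples", "n_channels", "subjects"))
    if (is.null(meta[[f]]))
      stop("fixture metadata missing field '", f, "'")
  mtg <- read_montage(file.path(path, "montage.tsv"))
  n <- length(mtg$names)
  if (meta$n_channels != n)
    stop("metadata n_channels (", meta$n_channels,
         ") does not match montage (", n, ")")
  S <- meta$n_samples
  subjects <- lapply(meta$subjects, function(s) {
    for (f in c("id", "label", "file", "n_trials"))
      if (is.null(s[[f]]))
        stop("fixture metadata missing field '", f, "' for a subject")
    flat <- as.matrix(utils::read.csv(file.path(path, s$file),
                                      header = FALSE))
    if (ncol(flat) != S || nrow(flat) != s$n_trials * n)
      stop("dimension mismatch for subject '", s$id, "': expected ",
           s$n_trials * n, " x ", S, ", got ", nrow(flat), " x ", ncol(flat))
    arr <- aperm(array(t(flat), dim = c(S, n, s$n_trials)), c(3, 2, 1))
    tv <- if (is.null(s$trial_valid)) rep(TRUE, s$n_trials)
          else as.logical(unlist(s$trial_valid))
    list(id = s$id,
         epochs = epoch_set(arr, meta$fs, meta$t0_ms, tv, subject_id = s$id),
         label = s$label)
  })
  cohort_dataset(subjects, mtg)
}

#' Write / read a named square matrix as delimited text
#'
#' Tab-separated grid with electrode names on the header row and first
#' column; 12 significant digits; `NaN` entries are written literally as
#' `nan`, never dropped.
#'
#' @param m square numeric matrix with identical row/column names.
#' @param path target file.
#' @export
write_matrix <- function(m, path) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("write_matrix expects a square matrix, got ",
         paste(dim(m), collapse = " x "))
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix must carry electrode names on both dimensions")
  txt <- matrix(formatC(m, digits = 12, format = "g"), nrow = nrow(m))
  txt[is.nan(m)] <- "nan"
  out <- cbind(rownames(m), txt)
  header <- c("", colnames(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(apply(out, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_matrix
#' @return For `read_matrix`, the named numeric matrix (with `NaN`
#'   restored).
#' @export
read_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1,
                           na.strings = character(0))
  m <- as.matrix(tab)
  suppressWarnings(storage.mode(m) <- "double")
  m
}
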