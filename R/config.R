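#' Analysis run configuration
#'
#' Collects the tunable parameters of the connectivity pipeline.  Defaults
#' follow the study conditions the pipeline targets: 0.1-30 Hz broadband,
#' candidate window sizes 50/100/150/200 ms with 90% overlap, a small lag
#' limit of 20 ms, the post-stimulus analysis interval 200-450 ms, the
#' first 11 stimulus responses aggregated by their mean, and a 75 uV
#' absolute-amplitude rejection threshold.
#'
#' @param band_low,band_high broadband filter edges in Hz.
#' @param band_subsets list of band specifications (see
#'   [enumerate_band_subsets()]); each entry is a list with `name` and an
#'   `intervals` matrix (rows = (low, high) Hz).  Default: the full band.
#' @param window_sizes_ms candidate correlation window sizes W (ms).
#' @param overlap_fraction window overlap in `[0, 1)`; step = W*(1-overlap).
#' @param lag_max_ms maximum |lag| searched, in ms.
#' @param interval_ms analysis interval `[start, end)` post-stimulus, ms.
#' @param epoch_ms epoch duration in ms.
#' @param n_stimuli number of (valid) trials used from the recording start.
#' @param trial_aggregate one of `"mean"`, `"median"`, `"max"`.
#' @param reject_uv amplitude rejection threshold (uV), applied to filtered,
#'   pre-normalization data.
#' @param min_valid_trials fewer valid trials than this raises a warning.
#' @param fisher_denominator `"group_sd"` (standard Fisher discriminant on
#'   per-subject values) or `"printed"` (literal dispersion-of-dispersions
#'   reading, degenerate and floored).
#' @param sd_type `"population"` (divide by N) or `"sample"`.
#' @param seed integer seed recorded for provenance.
#' @return A list of class `run_config`.
#' @export
run_config <- function(band_low = 0.1, band_high = 30,
                       band_subsets = NULL,
                       window_sizes_ms = c(50, 100, 150, 200),
                       overlap_fraction = 0.9,
                       lag_max_ms = 20,
                       interval_ms = c(200, 450),
                       epoch_ms = 1200,
                       n_stimuli = 11,
                       trial_aggregate = c("mean", "median", "max"),
                       reject_uv = 75,
                       min_valid_trials = 3,
                       fisher_denominator = c("group_sd", "printed"),
                       sd_type = c("population", "sample"),
                       seed = 1L) {
  trial_aggregate <- match.arg(trial_aggregate)
  fisher_denominator <- match.arg(fisher_denominator)
  sd_type <- match.arg(sd_type)
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  if (lag_max_ms < 0) stop("lag_max_ms must be >= 0")
  if (length(interval_ms) != 2L || interval_ms[1] >= interval_ms[2])
    stop("interval_ms must be an increasing [start, end) pair")
  if (is.null(band_subsets))
    band_subsets <- list(list(name = "full",
                              intervals = matrix(c(band_low, band_high),
                                                 ncol = 2)))
  structure(list(band_low = band_low, band_high = band_high,
                 band_subsets = band_subsets,
                 window_sizes_ms = sort(window_sizes_ms),
                 overlap_fraction = overlap_fraction,
                 lag_max_ms = lag_max_ms,
                 interval_ms = as.numeric(interval_ms),
                 epoch_ms = epoch_ms,
                 n_stimuli = as.integer(n_stimuli),
                 trial_aggregate = trial_aggregate,
                 reject_uv = reject_uv,
                 min_valid_trials = as.integer(min_valid_trials),
                 fisher_denominator = fisher_denominator,
                 sd_type = sd_type,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Feature-selection configuration
#'
#' @param retain_fraction fraction of candidate features kept by the
#'   between-group variance (Fisher) filter; the study default is 0.10.
#' @param K1_grid fractions of the electrode count tried for the electrode
#'   limit K1.
#' @param K2_grid fractions of the surviving feature count kept after
#'   Laplacian scoring.
#' @param laplacian_k neighbors of the subject kNN similarity graph
#'   (clamped to N-2 when the training fold is small).
#' @param K2_count optional integer override: keep exactly this many
#'   features instead of a fraction.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(retain_fraction = 0.10,
                             K1_grid = seq(0.1, 1, by = 0.1),
                             K2_grid = c(0.05, 0.10),
                             laplacian_k = 5L,
                             K2_count = NULL) {
  stopifnot(retain_fraction > 0, retain_fraction <= 1,
            all(K1_grid > 0), all(K1_grid <= 1),
            all(K2_grid > 0), all(K2_grid <= 1))
  structure(list(retain_fraction = retain_fraction, K1_grid = K1_grid,
                 K2_grid = K2_grid, laplacian_k = as.integer(laplacian_k),
                 K2_count = K2_count),
            class = "selection_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Recognized keys mirror the arguments of [run_config()] and
#' [selection_config()] under top-level sections `run` and `selection`;
#' unknown keys are rejected to catch typos.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return list with elements `run` ([run_config()]) and `selection`
#'   ([selection_config()]), plus any `simulate` / `io` sections verbatim.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  build <- function(args, fn, what) {
    if (is.null(args)) return(fn())
    ok <- names(formals(fn))
    bad <- setdiff(names(args), ok)
    if (length(bad))
      stop("unknown ", what, " config key(s): ", paste(bad, collapse = ", "))
    do.call(fn, args)
  }
  list(run = build(raw$run, run_config, "run"),
       selection = build(raw$selection, selection_config, "selection"),
       simulate = raw$simulate, io = raw$io, mode = raw$mode %||% "full",
       n_perm = raw$n_perm %||% 0L)
}
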