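## End-to-end runner: config in, artifacts + replayable report out.

#' Export group maps as a long coordinate table
#'
#' One row per (reference electrode, target electrode): scalp coordinates,
#' per-class map values and the Fisher score -- ready for any plotting
#' layer (scalp topographies, heatmaps).
#'
#' @param maps a [group_maps()] result.
#' @param montage the [montage()] the maps were computed on.
#' @return data frame with columns `reference`, `electrode`, `x`, `y`,
#'   `healthy`, `patient`, `fisher`.
#' @export
export_topography <- function(maps, montage) {
  stopifnot(inherits(maps, "group_maps"), inherits(montage, "eeg_montage"))
  nm <- montage$names
  n <- length(nm)
  out <- expand.grid(electrode = nm, reference = nm,
                     stringsAsFactors = FALSE)[, 2:1]
  out$x <- montage$positions[out$electrode, "x"]
  out$y <- montage$positions[out$electrode, "y"]
  out$healthy <- as.numeric(t(maps$cm$healthy))
  out$patient <- as.numeric(t(maps$cm$patient))
  out$fisher <- as.numeric(t(maps$fisher))
  rownames(out) <- NULL
  out
}

#' Run the whole pipeline from a configuration file
#'
#' Stages: obtain a cohort (simulate, or read an epoch fixture), prepare
#' (filter / reject / normalize / aggregate / connectivity tensors), build
#' group maps for the configuration chosen on the full cohort, run
#' leave-one-out classification (and optionally a permutation test), and
#' write all artifacts plus a replayable JSON run report into `outdir`.
#'
#' @param config path to a YAML/JSON config (see [read_run_config()]), or
#'   the list it returns.  The `simulate` section holds
#'   [synthetic_spec()] arguments; alternatively `io$fixture` points at an
#'   epoch-fixture directory.
#' @param outdir output directory (created).
#' @return The run report, invisibly; artifacts are written to `outdir`.
#' @export
run_pipeline <- function(config, outdir) {
  cfgs <- if (is.character(config)) read_run_config(config) else config
  cfg <- cfgs$run; sel_cfg <- cfgs$selection
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfgs$simulate)) {
    spec <- do.call(synthetic_spec, cfgs$simulate)
    gen <- generate_cohort(spec)
    cohort <- gen$cohort
    source_desc <- list(kind = "simulate", seed = spec$seed,
                        n_per_group = spec$n_per_group)
  } else if (!is.null(cfgs$io$fixture)) {
    cohort <- read_epoch_fixture(cfgs$io$fixture)
    source_desc <- list(kind = "fixture", path = cfgs$io$fixture)
  } else stop("config must provide a 'simulate' section or io$fixture")
  mode <- if (identical(cfgs$mode, "direct-only")) "direct" else "full"
  prep <- prepare_cohort(cohort, cfg)
  # full-cohort maps for the reporting configuration
  key <- as.character(select_window_size(prep$tensors, prep$labels,
                                         sd_type = cfg$sd_type))
  gm <- group_maps(prep$tensors[[key]], prep$labels, sd_type = cfg$sd_type,
                   denominator = cfg$fisher_denominator)
  write_matrix(gm$cm$healthy, file.path(outdir, "cm_healthy.tsv"))
  write_matrix(gm$cm$patient, file.path(outdir, "cm_patient.tsv"))
  write_matrix(gm$fisher, file.path(outdir, "fisher.tsv"))
  topo <- export_topography(gm, cohort$montage)
  utils::write.table(topo, file.path(outdir, "topography.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cv <- loo_cv(prepared = prep, sel_cfg = sel_cfg, mode = mode)
  if ((cfgs$n_perm %||% 0) >= 19) {
    pt <- permutation_pvalue(prepared = prep, sel_cfg = sel_cfg,
                             mode = mode, n_perm = cfgs$n_perm,
                             seed = cfg$seed, observed = cv)
    cv <- pt$cv
  }
  cm_conf <- cv$confusion
  utils::write.table(cbind(truth = rownames(cm_conf), as.data.frame(cm_conf)),
                     file.path(outdir, "confusion.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  report <- list(
    tool = "connmaps", version = as.character(utils::packageVersion("connmaps")),
    source = source_desc,
    config = list(run = unclass(cfg), selection = unclass(sel_cfg),
                  mode = mode, n_perm = cfgs$n_perm %||% 0),
    seeds = list(run = cfg$seed),
    stages = list(
      rejected_trials = stats::setNames(as.list(prep$reject_counts), prep$ids),
      trials_aggregated = stats::setNames(as.list(prep$n_used), prep$ids),
      configuration = key,
      configurations_available = names(prep$tensors)),
    results = list(accuracy = cv$accuracy, sensitivity = cv$sensitivity,
                   specificity = cv$specificity, p_value = cv$p_value,
                   predictions = stats::setNames(as.list(cv$predicted), prep$ids),
                   fold_features = cv$fold_features))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(cv[c("ids", "truth", "predicted", "margin",
                            "accuracy", "sensitivity", "specificity",
                            "p_value", "mode")],
                       file.path(outdir, "cv_result.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
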