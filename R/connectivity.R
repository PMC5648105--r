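## Connectivity core: the lag-maximized windowed cross-correlation, per
## subject connectivity matrices, per-group maps (CM, CM_STD) and the
## Fisher discrimination matrix.

#' Lag-maximized Pearson correlation between two signals
#'
#' For every integer lag `phi` in `[-lag_max, lag_max]`, the Pearson
#' correlation between `x[t]` and `y[t + phi]` is computed over their
#' overlapping samples; when `y` is longer than `x` (a window cut from a
#' full epoch), `y_start` gives the index of `y` aligned with `x[1]` so the
#' overlap can stay complete for every lag.  The maximum and its lag are
#' returned; ties resolve to the smallest `|phi|`, then to the negative
#' lag.  Zero-variance overlaps are skipped; if every lag is skipped the
#' signal pair is degenerate and an error is raised.
#'
#' @param x window signal (length >= 8).
#' @param y second signal, at least as long as `x`.
#' @param lag_max maximum absolute lag in samples.
#' @param y_start index of `y` aligned with `x[1]` (default 1).
#' @param min_overlap minimum overlapping samples for a lag to count.
#' @return list with `r` (maximum correlation) and `lag` (samples).
#' @export
lagged_correlation <- function(x, y, lag_max, y_start = 1L,
                               min_overlap = 8L) {
  if (length(x) < 8L) stop("window must hold at least 8 samples")
  if (length(y) < length(x)) stop("y must be at least as long as x")
  res <- lag_scan_pair_cpp(c(rep(0, y_start - 1L), x), as.numeric(y),
                           as.integer(y_start - 1L), length(x),
                           as.integer(lag_max), as.integer(min_overlap))
  if (!res$ok)
    stop("zero variance at every lag; cannot correlate")
  list(r = res$r, lag = res$lag)
}

#' Per-subject connectivity matrix
#'
#' Entry (A, B) is the maximum over the window grid of the lag-maximized
#' windowed correlation between channels A and B of the trial-aggregated
#' signal; the lag at the maximizing (window, lag) is recorded and the
#' diagonal is fixed at 1.
#'
#' @param aggregated channels x samples matrix from [aggregate_trials()].
#' @param grid a [make_window_grid()].
#' @param lag_max_samp maximum absolute lag in samples.
#' @param channel_names names for the matrix dimensions.
#' @param min_overlap minimum overlapping samples per evaluated lag.
#' @return list with `values` (n x n, in `[-1, 1]`) and `lags` (n x n,
#'   samples).
#' @export
subject_connectivity <- function(aggregated, grid, lag_max_samp,
                                 channel_names = rownames(aggregated),
                                 min_overlap = 8L) {
  stopifnot(is.matrix(aggregated), inherits(grid, "window_grid"))
  res <- lag_scan_matrix_cpp(aggregated, as.integer(grid$starts - 1L),
                             grid$w_samp, as.integer(lag_max_samp),
                             as.integer(min_overlap))
  if (!all(res$ok)) {
    bad <- which(!res$ok, arr.ind = TRUE)[1, ]
    stop("zero variance for channel pair (",
         channel_names[bad[1]] %||% bad[1], ", ",
         channel_names[bad[2]] %||% bad[2], ")")
  }
  dimnames(res$r) <- dimnames(res$lag) <- list(channel_names, channel_names)
  list(values = res$r, lags = res$lag)
}

#' Stack per-subject connectivity matrices into a tensor
#'
#' @param aggregates list (per subject) of channels x samples matrices.
#' @param grid a [make_window_grid()].
#' @param lag_max_samp maximum absolute lag in samples.
#' @param channel_names electrode names.
#' @return list of class `conn_tensor`: `values` and `lags` arrays of
#'   dimension n x n x subjects, plus the grid and lag configuration.
#' @export
connectivity_tensor <- function(aggregates, grid, lag_max_samp,
                                channel_names = NULL) {
  n <- nrow(aggregates[[1]])
  S <- length(aggregates)
  vals <- array(NA_real_, c(n, n, S))
  lags <- array(NA_integer_, c(n, n, S))
  for (s in seq_len(S)) {
    sc <- subject_connectivity(aggregates[[s]], grid, lag_max_samp,
                               channel_names)
    vals[, , s] <- sc$values
    lags[, , s] <- sc$lags
  }
  dimnames(vals) <- dimnames(lags) <- list(channel_names, channel_names, NULL)
  structure(list(values = vals, lags = lags, grid = grid,
                 lag_max_samp = lag_max_samp),
            class = "conn_tensor")
}

# population or sample std of a vector
.grp_sd <- function(v, type) {
  if (type == "sample") stats::sd(v)
  else sqrt(mean((v - mean(v))^2))
}

#' Fisher score of a two-group sample
#'
#' `|mean0 - mean1| / sqrt(sd0^2 + sd1^2)` with population (divide-by-N)
#' standard deviations by default and the denominator floored at 1e-12.
#' Vectorized over the columns of a matrix.
#'
#' @param x numeric matrix (subjects x features) or vector.
#' @param labels factor/character with two groups aligned to rows.
#' @param sd_type `"population"` or `"sample"`.
#' @return numeric vector of nonnegative scores, one per column.
#' @export
fisher_score <- function(x, labels, sd_type = "population") {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  g <- labels == levels(factor(labels))[1]
  x0 <- x[g, , drop = FALSE]; x1 <- x[!g, , drop = FALSE]
  m0 <- colMeans(x0); m1 <- colMeans(x1)
  v0 <- colMeans(x0 * x0) - m0^2
  v1 <- colMeans(x1 * x1) - m1^2
  if (sd_type == "sample") {
    v0 <- v0 * nrow(x0) / (nrow(x0) - 1)
    v1 <- v1 * nrow(x1) / (nrow(x1) - 1)
  }
  v0 <- pmax(v0, 0); v1 <- pmax(v1, 0)
  abs(m0 - m1) / pmax(sqrt(v0 + v1), .EPS_FLOOR)
}

#' Group connectivity maps and the Fisher matrix
#'
#' CM is the per-class mean connectivity matrix over subjects; CM_STD the
#' per-class std (population formula by default); FISHER(A,B) =
#' `|CM_healthy - CM_patient| / sqrt(CM_STD_healthy^2 + CM_STD_patient^2)`
#' with the denominator floored at 1e-12.  `denominator = "printed"`
#' replaces the denominator by the dispersion *of* the group dispersion
#' scalars, which degenerates to the floor when each subject contributes a
#' single aggregated value; it is provided for comparability only.
#'
#' @param tensor a [connectivity_tensor()] (or bare n x n x S array).
#' @param labels factor healthy/patient per subject.
#' @param sd_type `"population"` or `"sample"`.
#' @param denominator `"group_sd"` or `"printed"`.
#' @return list of class `group_maps`: `cm` (list healthy/patient),
#'   `cm_std`, `fisher`, `n_per_class`.
#' @export
group_maps <- function(tensor, labels, sd_type = "population",
                       denominator = c("group_sd", "printed")) {
  denominator <- match.arg(denominator)
  vals <- if (inherits(tensor, "conn_tensor")) tensor$values else tensor
  labels <- factor(labels, levels = c("healthy", "patient"))
  if (any(table(labels) < 2))
    stop("need at least 2 subjects per class for group maps")
  sel <- list(healthy = which(labels == "healthy"),
              patient = which(labels == "patient"))
  cm <- lapply(sel, function(ix) apply(vals[, , ix, drop = FALSE], c(1, 2), mean))
  cm_std <- lapply(sel, function(ix)
    apply(vals[, , ix, drop = FALSE], c(1, 2), .grp_sd, type = sd_type))
  num <- abs(cm$healthy - cm$patient)
  den <- if (denominator == "group_sd")
    sqrt(cm_std$healthy^2 + cm_std$patient^2)
  else matrix(0, nrow(num), ncol(num), dimnames = dimnames(num))
  fisher <- num / pmax(den, .EPS_FLOOR)
  diag(fisher) <- 0
  structure(list(cm = cm, cm_std = cm_std, fisher = fisher,
                 n_per_class = as.integer(table(labels)),
                 denominator = denominator),
            class = "group_maps")
}

#' @export
print.group_maps <- function(x, ...) {
  cat(sprintf("<group_maps> %d x %d electrodes, %d healthy / %d patient; max Fisher %.3f\n",
              nrow(x$fisher), ncol(x$fisher), x$n_per_class[1],
              x$n_per_class[2], max(x$fisher)))
  invisible(x)
}

# mean of the m largest off-diagonal upper-triangle Fisher entries; the
# training-fold criterion used to pick a (band, window-size) configuration
.fisher_criterion <- function(fisher, m = 10L) {
  v <- fisher[upper.tri(fisher)]
  mean(sort(v, decreasing = TRUE)[seq_len(min(m, length(v)))])
}

#' Select the best (band, window-size) configuration on training subjects
#'
#' Each candidate configuration's tensor is scored by the mean of the
#' top-10 entries of its Fisher matrix computed on the training subjects
#' only; the maximizing candidate wins and ties resolve to the earlier
#' candidate (candidates are ordered by band, then ascending window size,
#' so ties prefer the smaller window).
#'
#' @param tensors named list of [connectivity_tensor()] candidates.
#' @param labels training labels aligned to the tensor's subject dimension.
#' @param train_idx indices of training subjects (default: all).
#' @param top_m entries averaged by the criterion.
#' @param sd_type passed to [group_maps()].
#' @return name (or index, when unnamed) of the winning configuration, with
#'   the per-candidate criterion in the `criterion` attribute.
#' @export
select_window_size <- function(tensors, labels, train_idx = NULL,
                               top_m = 10L, sd_type = "population") {
  if (length(tensors) == 1L)
    return(structure(names(tensors) %||% 1L, criterion = NA_real_))
  crit <- vapply(tensors, function(tn) {
    vals <- tn$values
    if (!is.null(train_idx)) {
      vals <- vals[, , train_idx, drop = FALSE]
      labs <- labels[train_idx]
    } else labs <- labels
    .fisher_criterion(group_maps(vals, labs, sd_type = sd_type)$fisher, top_m)
  }, numeric(1))
  best <- which.max(crit)   # first maximum: earlier candidate wins ties
  structure(names(tensors)[best] %||% best, criterion = crit)
}
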