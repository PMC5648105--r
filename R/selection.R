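## Feature selection: between-group variance (Fisher) filter, Laplacian
## scores on a subject similarity graph, electrode-limited K1/K2 selection
## with an inner leave-one-out grid search.

#' Keep the top fraction of features by between-group Fisher score
#'
#' Features are ranked by the between-class Fisher criterion (see
#' [fisher_rel()]) and the top `ceil(retain_fraction * M)` are kept; ties
#' resolve to the lower column index.
#'
#' @param ft a [feature_table()].
#' @param labels healthy/patient per subject.
#' @param retain_fraction fraction kept (study default 0.10).
#' @return list with `table` (filtered [feature_table()]), `kept` (original
#'   column indices) and `scores`.
#' @export
variance_filter <- function(ft, labels, retain_fraction = 0.10) {
  M <- ncol(ft$mat)
  if (M < 1L) stop("variance_filter needs at least one feature")
  scores <- fisher_rel(ft, labels)
  k <- ceiling(retain_fraction * M)
  ord <- order(-scores, seq_len(M))
  kept <- sort(ord[seq_len(k)])
  list(table = ft_subset(ft, kept), kept = kept, scores = scores)
}

#' Laplacian score of each feature over a subject similarity graph
#'
#' Builds a symmetric k-nearest-neighbor graph over subjects in the feature
#' space with heat-kernel weights (kernel width = median squared pairwise
#' distance), then scores each feature f by the locality-preserving
#' variance ratio `f~' L f~ / f~' D f~`, where L is the graph Laplacian, D
#' the degree matrix and `f~` the degree-centered feature.  Lower scores
#' mean the feature respects the graph's local structure.  Constant
#' features get the worst (largest) score and are flagged.
#'
#' @param ft a [feature_table()] or subjects x features matrix.
#' @param k neighbors per subject (clamped to N-2).
#' @return numeric vector of scores (lower = better); constant columns are
#'   listed in the `degenerate` attribute.
#' @export
laplacian_score <- function(ft, k = 5L) {
  X <- if (inherits(ft, "feature_table")) ft$mat else ft
  N <- nrow(X)
  if (N < 4L) stop("Laplacian score needs at least 4 subjects")
  k <- max(1L, min(as.integer(k), N - 2L))
  D2 <- as.matrix(stats::dist(X))^2
  width <- stats::median(D2[upper.tri(D2)])
  if (width <= 0) width <- 1
  W <- exp(-D2 / width)
  # symmetric kNN adjacency: keep an edge when either endpoint ranks the
  # other among its k nearest
  adj <- matrix(FALSE, N, N)
  for (i in seq_len(N)) {
    nb <- order(D2[i, ])[2:(k + 1L)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  W[!adj] <- 0
  diag(W) <- 0
  deg <- rowSums(W)
  scores <- vapply(seq_len(ncol(X)), function(j) {
    f <- X[, j]
    fc <- f - sum(f * deg) / sum(deg)
    den <- sum(deg * fc^2)
    if (den < .EPS_FLOOR) return(Inf)
    num <- sum(fc * (deg * fc - as.numeric(W %*% fc)))  # f~' L f~
    num / den
  }, numeric(1))
  degen <- which(!is.finite(scores))
  if (length(degen)) {
    worst <- if (all(!is.finite(scores))) 1 else max(scores[is.finite(scores)])
    scores[degen] <- worst + 1
  }
  structure(scores, degenerate = degen)
}

# Gaussian two-class fit on a plain matrix (internal; exported wrapper in
# classify.R operates on feature tables)
.fit_gauss <- function(X, labels, priors = c(0.5, 0.5)) {
  g <- labels == "healthy"
  if (sum(g) < 2 || sum(!g) < 2)
    stop("need at least 2 training subjects per class")
  pvar <- function(M) colMeans(sweep(M, 2, colMeans(M))^2)
  list(mean_healthy = colMeans(X[g, , drop = FALSE]),
       var_healthy = pmax(pvar(X[g, , drop = FALSE]), .EPS_FLOOR),
       mean_patient = colMeans(X[!g, , drop = FALSE]),
       var_patient = pmax(pvar(X[!g, , drop = FALSE]), .EPS_FLOOR),
       priors = priors)
}

.gauss_ll <- function(model, x, class) {
  m <- model[[paste0("mean_", class)]]
  v <- model[[paste0("var_", class)]]
  sum(-0.5 * log(2 * pi * v) - (x - m)^2 / (2 * v)) +
    log(model$priors[if (class == "healthy") 1 else 2])
}

.gauss_predict <- function(model, x) {
  lh <- .gauss_ll(model, x, "healthy")
  lp <- .gauss_ll(model, x, "patient")
  label <- if (lp > lh) "patient" else "healthy"   # tie -> healthy
  list(label = label, margin = abs(lp - lh), tie = lp == lh,
       ll_healthy = lh, ll_patient = lp)
}

# inner leave-one-out accuracy of the Gaussian model on fixed columns
.inner_loo_acc <- function(X, labels) {
  N <- nrow(X)
  ok <- 0L
  for (i in seq_len(N)) {
    tr <- setdiff(seq_len(N), i)
    if (min(table(labels[tr])) < 2) next
    mod <- .fit_gauss(X[tr, , drop = FALSE], labels[tr])
    if (.gauss_predict(mod, X[i, ])$label == labels[i]) ok <- ok + 1L
  }
  ok / N
}

# one (K1, K2) selection pass given precomputed Fisher scores: electrode
# limit by top-K1 mean Fisher, then Laplacian-ranked feature cut.  `lap`
# holds per-feature Laplacian scores (the subject graph is label-free, so
# it is built once on the full training rows and reused).
.select_cut <- function(desc, fscores, K1, K2_frac, K2_count, lap) {
  refs <- desc$ref
  electrodes <- unique(refs)
  el_score <- vapply(electrodes, function(e) {
    s <- sort(fscores[refs == e], decreasing = TRUE)
    mean(s[seq_len(min(K1, length(s)))])
  }, numeric(1))
  keep_el <- electrodes[order(-el_score, match(electrodes, refs))[
    seq_len(min(K1, length(electrodes)))]]
  surv <- which(refs %in% keep_el)
  if (!length(surv)) return(NULL)
  K2 <- if (!is.null(K2_count)) min(K2_count, length(surv))
        else max(1L, ceiling(K2_frac * length(surv)))
  sel <- surv[order(lap[surv], surv)[seq_len(K2)]]
  list(selected = sort(sel), electrodes = keep_el, K2 = K2)
}

#' Electrode-limited feature selection with a K1/K2 grid
#'
#' Features are grouped by their source/reference electrode.  For a
#' candidate K1 (a fraction of the electrode count), each electrode is
#' scored by the mean of its top-K1 feature Fisher scores and the top-K1
#' electrodes are kept; among the surviving features, the K2 fraction with
#' the best (lowest) Laplacian score is retained.  Candidate (K1, K2)
#' cells are arbitrated by inner leave-one-out accuracy on the training
#' subjects, with the label-dependent ranking recomputed inside every
#' inner fold (the Laplacian scores are label-free and computed once on
#' the training rows); ties resolve to fewer electrodes, then fewer
#' features.  All statistics use the supplied (training) rows only.
#'
#' @param ft a [feature_table()] of candidate features (training rows).
#' @param labels training labels.
#' @param cfg a [selection_config()].
#' @param n_electrodes electrode count of the montage.
#' @return list with `selected` (column indices into `ft`), `K1`, `K2`,
#'   `electrodes` (kept electrode names), `inner_accuracy`, and the full
#'   `grid` of candidate results.
#' @export
select_features <- function(ft, labels, cfg = selection_config(),
                            n_electrodes) {
  M <- ncol(ft$mat)
  if (M < 1L) stop("no candidate features to select from")
  N <- nrow(ft$mat)
  lap <- laplacian_score(ft$mat, cfg$laplacian_k)
  grid <- expand.grid(K1 = cfg$K1_grid, K2 = cfg$K2_grid)
  K1s <- as.integer(pmax(1, ceiling(grid$K1 * n_electrodes)))
  cells <- which(!duplicated(data.frame(K1s, grid$K2)))
  ok <- integer(length(cells)); n_eval <- integer(length(cells))
  # inner leave-one-out outermost so the per-fold Fisher scores are shared
  # by every grid cell
  for (i in seq_len(N)) {
    tr <- setdiff(seq_len(N), i)
    if (min(table(labels[tr])) < 2) next
    Xtr <- ft$mat[tr, , drop = FALSE]
    fs_tr <- fisher_score(Xtr, labels[tr])
    hit_cache <- new.env(parent = emptyenv())  # cells often share a set
    for (ci in seq_along(cells)) {
      gi <- cells[ci]
      s <- .select_cut(ft$desc, fs_tr, K1s[gi], grid$K2[gi], cfg$K2_count,
                       lap)
      if (is.null(s)) next
      n_eval[ci] <- n_eval[ci] + 1L
      key <- paste(s$selected, collapse = ",")
      hit <- hit_cache[[key]]
      if (is.null(hit)) {
        mod <- .fit_gauss(Xtr[, s$selected, drop = FALSE], labels[tr])
        hit <- .gauss_predict(mod, ft$mat[i, s$selected])$label == labels[i]
        hit_cache[[key]] <- hit
      }
      if (hit) ok[ci] <- ok[ci] + 1L
    }
  }
  fs_all <- fisher_score(ft$mat, labels)
  results <- list()
  for (ci in seq_along(cells)) {
    gi <- cells[ci]
    if (!n_eval[ci]) next
    final <- .select_cut(ft$desc, fs_all, K1s[gi], grid$K2[gi],
                         cfg$K2_count, lap)
    if (is.null(final)) next
    results[[length(results) + 1L]] <-
      list(selected = final$selected, K1 = K1s[gi], K2 = final$K2,
           electrodes = final$electrodes, inner_accuracy = ok[ci] / N,
           K1_frac = grid$K1[gi], K2_frac = grid$K2[gi])
  }
  if (!length(results))
    stop("every (K1, K2) grid cell produced an empty feature set")
  accs <- vapply(results, `[[`, numeric(1), "inner_accuracy")
  k1s <- vapply(results, `[[`, numeric(1), "K1")
  k2s <- vapply(results, `[[`, numeric(1), "K2")
  best <- order(-accs, k1s, k2s)[1]
  out <- results[[best]]
  out$grid <- results
  out
}
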