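## Reference-relative features: per-subject direct connectivity columns,
## REL differences seen from a reference electrode, MUL products sharing a
## reference, Fisher scoring of columns and distance pruning.

#' Feature table
#'
#' A subjects x features matrix plus one descriptor row per column:
#' `kind` (`"CM"` direct connectivity, `"REL"`, `"MUL"`), the reference
#' electrode `ref` (for CM columns the first electrode of the pair, which
#' also defines the electrode grouping of the selection step), target
#' electrodes `e1 ... e4`, and a unique `name`.
#'
#' @param mat numeric matrix, subjects x features.
#' @param desc data frame of per-column descriptors.
#' @return list of class `feature_table`.
#' @export
feature_table <- function(mat, desc) {
  stopifnot(is.matrix(mat), nrow(desc) == ncol(mat))
  if (anyDuplicated(desc$name)) stop("feature names must be unique")
  if (anyNA(mat)) stop("feature table contains NA after construction")
  colnames(mat) <- desc$name
  structure(list(mat = mat, desc = desc), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d features (%s)\n",
              nrow(x$mat), ncol(x$mat),
              paste(sprintf("%s:%d", names(table(x$desc$kind)),
                            table(x$desc$kind)), collapse = ", ")))
  invisible(x)
}

ft_subset <- function(ft, idx) feature_table(ft$mat[, idx, drop = FALSE],
                                             ft$desc[idx, , drop = FALSE])

ft_cbind <- function(a, b) {
  if (is.null(b) || ncol(b$mat) == 0) return(a)
  feature_table(cbind(a$mat, b$mat), rbind(a$desc, b$desc))
}

.desc_row <- function(kind, ref, e1 = NA, e2 = NA, e3 = NA, e4 = NA, name) {
  data.frame(kind = kind, ref = ref, e1 = e1, e2 = e2, e3 = e3, e4 = e4,
             name = name, stringsAsFactors = FALSE)
}

#' Direct connectivity columns
#'
#' One column per unordered electrode pair A < B (montage order): the
#' per-subject connectivity value conn(A, B).  These are the only columns
#' available in direct-only (ablation) mode.
#'
#' @param tensor a [connectivity_tensor()].
#' @return A [feature_table()] with `kind == "CM"`.
#' @export
cm_features <- function(tensor) {
  vals <- tensor$values
  nm <- dimnames(vals)[[1]]
  n <- dim(vals)[1]; S <- dim(vals)[3]
  pairs <- utils::combn(n, 2)
  mat <- matrix(NA_real_, S, ncol(pairs))
  desc <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    mat[, k] <- vals[a, b, ]
    desc[[k]] <- .desc_row("CM", nm[a], nm[a], nm[b],
                           name = sprintf("CM|%s-%s", nm[a], nm[b]))
  }
  feature_table(mat, do.call(rbind, desc))
}

#' Reference-relative features
#'
#' For every reference electrode C and unordered target pair {A, B} with
#' A < B in montage order (A, B != C), the per-subject value
#' `REL_C(A, B) = conn_C(A) - conn_C(B)`: the difference between the pair's
#' connectivities as seen from C.  There are `n * choose(n-1, 2)` columns.
#'
#' @param tensor a [connectivity_tensor()].
#' @return A [feature_table()] with `kind == "REL"`.
#' @export
rel_features <- function(tensor) {
  vals <- tensor$values
  nm <- dimnames(vals)[[1]]
  n <- dim(vals)[1]; S <- dim(vals)[3]
  cols <- list(); desc <- list()
  for (C in seq_len(n)) {
    others <- setdiff(seq_len(n), C)
    prs <- utils::combn(others, 2)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1, k]; b <- prs[2, k]
      cols[[length(cols) + 1L]] <- vals[C, a, ] - vals[C, b, ]
      desc[[length(desc) + 1L]] <-
        .desc_row("REL", nm[C], nm[a], nm[b],
                  name = sprintf("REL|%s|%s-%s", nm[C], nm[a], nm[b]))
    }
  }
  feature_table(do.call(cbind, cols), do.call(rbind, desc))
}

#' Products of relative features sharing a reference
#'
#' For every unordered pair of *retained* REL columns that share the same
#' reference electrode C, the per-subject product
#' `MUL_C(A1,B1,A2,B2) = REL_C(A1,B1) * REL_C(A2,B2)`.  Requiring a shared
#' C amplifies multi-purpose reference electrodes, and restricting to
#' columns that survived the variance filter keeps the combinatorics
#' bounded.  Squares (the same REL twice) are excluded by default.
#'
#' @param rel a [feature_table()] of REL columns.
#' @param retained_idx indices of REL columns surviving the variance filter.
#' @param include_squares include `REL^2` terms.
#' @return A [feature_table()] with `kind == "MUL"`, or `NULL` when no
#'   reference has two retained columns.
#' @export
mul_features <- function(rel, retained_idx = seq_len(ncol(rel$mat)),
                         include_squares = FALSE) {
  keep <- retained_idx[rel$desc$kind[retained_idx] == "REL"]
  cols <- list(); desc <- list()
  for (C in unique(rel$desc$ref[keep])) {
    ix <- keep[rel$desc$ref[keep] == C]
    if (length(ix) < if (include_squares) 1L else 2L) next
    prs <- if (include_squares)
      cbind(utils::combn(ix, 2), rbind(ix, ix))
    else utils::combn(ix, 2)
    for (k in seq_len(ncol(prs))) {
      i <- prs[1, k]; j <- prs[2, k]
      d1 <- rel$desc[i, ]; d2 <- rel$desc[j, ]
      cols[[length(cols) + 1L]] <- rel$mat[, i] * rel$mat[, j]
      desc[[length(desc) + 1L]] <-
        .desc_row("MUL", C, d1$e1, d1$e2, d2$e1, d2$e2,
                  name = sprintf("MUL|%s|%s-%s|%s-%s", C, d1$e1, d1$e2,
                                 d2$e1, d2$e2))
    }
  }
  if (!length(cols)) return(NULL)
  feature_table(do.call(cbind, cols), do.call(rbind, desc))
}

#' Fisher scores of relative (or any) feature columns
#'
#' The between-group Fisher score of each column over per-subject values:
#' `|mean_healthy - mean_patient| / sqrt(sd_healthy^2 + sd_patient^2)`,
#' denominator floored at 1e-12.
#'
#' @param ft a [feature_table()] (or bare matrix).
#' @param labels healthy/patient per subject (row).
#' @param sd_type `"population"` or `"sample"`.
#' @return numeric vector of scores.
#' @export
fisher_rel <- function(ft, labels, sd_type = "population") {
  m <- if (inherits(ft, "feature_table")) ft$mat else ft
  fisher_score(m, labels, sd_type = sd_type)
}

#' Drop features whose reference sits too close to a target
#'
#' With a distance function over the montage, features whose reference-to-
#' target scalp distance falls below `threshold` are removed, keeping the
#' long-range features; `threshold = 0` disables pruning.  For CM columns
#' the "reference" is the first electrode of the pair; for REL/MUL columns
#' all targets must clear the threshold.
#'
#' @param ft a [feature_table()].
#' @param montage an [montage()] with positions.
#' @param threshold minimum reference-to-target distance (unitless).
#' @return The pruned [feature_table()]; empty result raises a warning.
#' @export
distance_prune <- function(ft, montage, threshold = 0) {
  if (threshold <= 0) return(ft)
  D <- montage_distance(montage)
  keep <- vapply(seq_len(nrow(ft$desc)), function(k) {
    d <- ft$desc[k, ]
    targets <- stats::na.omit(unlist(d[c("e1", "e2", "e3", "e4")]))
    targets <- setdiff(targets, d$ref)
    all(D[d$ref, targets] >= threshold)
  }, logical(1))
  if (!any(keep)) {
    warning("distance threshold ", threshold, " removed every feature")
    return(ft_subset(ft, integer(0)))
  }
  ft_subset(ft, which(keep))
}
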