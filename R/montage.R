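#' Electrode montage
#'
#' A montage is the ordered set of electrode names together with 2-D scalp
#' coordinates (unitless head-circle projection) and a coarse anatomical
#' region tag used when interpreting maps (posterior references vs frontal
#' targets).
#'
#' @param names character vector of unique electrode labels (10-20/10-10).
#' @param x,y numeric scalp coordinates, finite, same length as `names`.
#' @param region optional character vector of region tags; anything outside
#'   the known set is mapped to `"other"`.
#' @return An object of class `eeg_montage`: a list with `names`,
#'   `positions` (n x 2 matrix) and `region`.
#' @export
montage <- function(names, x, y, region = NULL) {
  names <- as.character(names)
  n <- length(names)
  if (n < 2L) stop("montage needs at least 2 electrodes")
  if (anyDuplicated(names)) stop("electrode names must be unique")
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != n || length(y) != n)
    stop("positions must match the number of electrodes")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("electrode positions must be finite")
  known <- c("posterior", "central", "frontal", "prefrontal", "temporal",
             "other")
  if (is.null(region)) region <- rep("other", n)
  region <- as.character(region)
  region[!region %in% known] <- "other"
  pos <- cbind(x = x, y = y)
  rownames(pos) <- names
  structure(list(names = names, positions = pos, region = region),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$names), " electrodes: ",
      paste(utils::head(x$names, 8), collapse = ", "),
      if (length(x$names) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Pairwise electrode distances
#'
#' Euclidean distances between scalp positions; used by [distance_prune()].
#'
#' @param m an [montage()] object.
#' @return n x n named distance matrix (unitless).
#' @export
montage_distance <- function(m) {
  stopifnot(inherits(m, "eeg_montage"))
  d <- as.matrix(stats::dist(m$positions))
  dimnames(d) <- list(m$names, m$names)
  d
}

#' Read / write a montage table
#'
#' Tab-separated dialect with columns `name`, `x`, `y`, `region`; unknown
#' region tags become `"other"`.
#'
#' @param path file path.
#' @export
read_montage <- function(path) {
  if (!file.exists(path)) stop("montage file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("montage table missing column(s): ", paste(miss, collapse = ", "))
  montage(tab$name, tab$x, tab$y, tab$region %||% NULL)
}

#' @rdname read_montage
#' @param m an [montage()] object.
#' @export
write_montage <- function(m, path) {
  stopifnot(inherits(m, "eeg_montage"))
  tab <- data.frame(name = m$names, x = m$positions[, "x"],
                    y = m$positions[, "y"], region = m$region)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Demonstration 8-electrode montage
#'
#' Two occipital/parietal electrodes (O1, O2, P7, P8), two central (Cz,
#' FCz) and two frontal (F1, F2) on an approximate 10-20 head-circle
#' projection.  This is the default montage of the synthetic cohort, where
#' the planted coupling runs from a posterior reference to a frontal
#' target.
#'
#' @return An [montage()] object with 8 electrodes.
#' @export
demo_montage <- function() {
  montage(
    names = c("O1", "O2", "P7", "P8", "Cz", "FCz", "F1", "F2"),
    x = c(-0.27, 0.27, -0.55, 0.55, 0, 0, -0.27, 0.27),
    y = c(-0.85, -0.85, -0.62, -0.62, 0, 0.25, 0.62, 0.62),
    region = c("posterior", "posterior", "posterior", "posterior",
               "central", "central", "frontal", "frontal"))
}

# generic circular montage used when the synthetic spec asks for a channel
# count without naming electrodes
circle_montage <- function(n) {
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  montage(sprintf("E%02d", seq_len(n)), cos(th), sin(th))
}
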