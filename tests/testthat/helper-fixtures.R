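# Shared builders and independent oracles used across the suite.

# tiny 4-electrode montage (posterior reference, frontal target)
tiny_montage <- function() {
  montage(c("O2", "P8", "Cz", "F2"),
          x = c(0.27, 0.55, 0, 0.27),
          y = c(-0.85, -0.62, 0, 0.62),
          region = c("posterior", "posterior", "central", "frontal"))
}

# small deterministic cohort: white-noise epochs, optional lagged coupling
# planted directly in the arrays (independent of the synth module)
tiny_cohort <- function(n_per_group = 3, n_trials = 4, n_ch = 4,
                        n_samp = 307, fs = 512, seed = 1) {
  set.seed(seed)
  mtg <- if (n_ch == 4) tiny_montage() else connmaps:::circle_montage(n_ch)
  subjects <- lapply(seq_len(2 * n_per_group), function(i) {
    arr <- array(rnorm(n_trials * n_ch * n_samp), c(n_trials, n_ch, n_samp))
    list(id = sprintf("s%02d", i),
         epochs = epoch_set(arr, fs, -200, subject_id = sprintf("s%02d", i)),
         label = if (i <= n_per_group) "healthy" else "patient")
  })
  cohort_dataset(subjects, mtg)
}

# brute-force lag-maximized windowed correlation: exhaustive loop over
# (window start, lag) with the same tie rules, pure R
brute_scan <- function(a, b, starts, w, lag_max, min_overlap = 8) {
  S <- length(b)
  best <- -Inf; best_lag <- NA; best_start <- NA; any_ok <- FALSE
  lag_order <- c(0, as.vector(rbind(-seq_len(lag_max), seq_len(lag_max))))
  for (s in starts) {
    for (phi in lag_order) {
      t_idx <- s:(s + w - 1)
      y_idx <- t_idx + phi
      ok <- y_idx >= 1 & y_idx <= S
      if (sum(ok) < min_overlap) next
      x <- a[t_idx[ok]]; y <- b[y_idx[ok]]
      if (sd(x) == 0 || sd(y) == 0) next
      r <- suppressWarnings(cor(x, y))
      if (!is.finite(r)) next
      any_ok <- TRUE
      if (r > best) { best <- r; best_lag <- phi; best_start <- s }
    }
  }
  list(ok = any_ok, r = best, lag = best_lag, start = best_start)
}

# brute-force Laplacian score from the definition (dense matrices)
brute_laplacian <- function(X, k) {
  N <- nrow(X)
  D2 <- as.matrix(dist(X))^2
  width <- median(D2[upper.tri(D2)]); if (width <= 0) width <- 1
  Wm <- exp(-D2 / width)
  adj <- matrix(FALSE, N, N)
  for (i in seq_len(N)) adj[i, order(D2[i, ])[2:(k + 1)]] <- TRUE
  adj <- adj | t(adj)
  Wm[!adj] <- 0; diag(Wm) <- 0
  Dm <- diag(rowSums(Wm)); L <- Dm - Wm
  ones <- rep(1, N)
  apply(X, 2, function(f) {
    fc <- f - as.numeric((t(f) %*% Dm %*% ones) / (t(ones) %*% Dm %*% ones))
    as.numeric((t(fc) %*% L %*% fc) / (t(fc) %*% Dm %*% fc))
  })
}

# deterministic montage-ordered pair of a Fisher matrix's largest entry
top_fisher_pair <- function(fisher) {
  w <- which(fisher == max(fisher), arr.ind = TRUE)[1, ]
  sort(c(rownames(fisher)[w[1]], colnames(fisher)[w[2]]))
}
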