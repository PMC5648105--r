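make_ft <- function(mat, refs = NULL) {
  M <- ncol(mat)
  if (is.null(refs)) refs <- paste0("E", seq_len(M))
  desc <- data.frame(kind = "CM", ref = refs, e1 = refs, e2 = "X",
                     e3 = NA, e4 = NA, name = paste0("f", seq_len(M)),
                     stringsAsFactors = FALSE)
  feature_table(mat, desc)
}

test_that("variance filter keeps the Fisher-top fraction with index ties", {
  set.seed(1)
  labels <- rep(c("healthy", "patient"), each = 5)
  base <- matrix(rnorm(10 * 100), 10)
  base[labels == "patient", 1:7] <- base[labels == "patient", 1:7] + 3
  ft <- make_ft(base)
  out <- variance_filter(ft, labels, 0.1)
  expect_equal(ncol(out$table$mat), 10)     # ceil(0.1 * 100)
  expect_true(all(1:7 %in% out$kept))
  # ceil on small tables
  out5 <- variance_filter(make_ft(base[, 1:5]), labels, 0.1)
  expect_equal(ncol(out5$table$mat), 1)
  # all-equal scores: first ceil(f * M) columns by index
  const <- matrix(rep(c(0, 1), each = 5), 10, 20)
  outc <- variance_filter(make_ft(const), labels, 0.25)
  expect_equal(outc$kept, 1:5)
})

test_that("Laplacian scores equal the brute-force formula and rank clusters", {
  set.seed(21)
  X <- matrix(rnorm(5 * 3), 5, 3)
  expect_equal(as.numeric(laplacian_score(X, 2)),
               brute_laplacian(X, 2), tolerance = 1e-12)
  # 6 subjects in two tight clusters: the cluster indicator scores better
  # (lower) than an independent random feature
  cl <- rep(c(0, 5), each = 3)
  Xc <- cbind(cl + rnorm(6, sd = 0.1),
              cl + rnorm(6, sd = 0.1),
              rnorm(6))
  ls <- laplacian_score(Xc, 2)
  expect_lt(ls[1], ls[3])
  # constant feature gets the worst score and is flagged
  Xd <- cbind(Xc, 7)
  ld <- laplacian_score(Xd, 2)
  expect_equal(which.max(ld), 4L)
  expect_equal(attr(ld, "degenerate"), 4L)
})

test_that("K1/K2 selection finds planted electrodes and honors tie-breaks", {
  set.seed(33)
  labels <- rep(c("healthy", "patient"), each = 8)
  # features grouped under 4 electrodes; only electrode E2's features carry
  # the class signal
  refs <- rep(paste0("E", 1:4), each = 5)
  mat <- matrix(rnorm(16 * 20), 16)
  sig <- which(refs == "E2")
  mat[labels == "patient", sig] <- mat[labels == "patient", sig] + 2.5
  ft <- make_ft(mat, refs)
  sel <- select_features(ft, labels, selection_config(K1_grid = c(0.25, 1),
                                                      K2_grid = c(0.5),
                                                      laplacian_k = 3),
                         n_electrodes = 4)
  expect_true("E2" %in% sel$electrodes)
  expect_true(all(sel$selected %in% sig))
  # no-op grid: K1 = all electrodes, K2 = all features
  sel_all <- select_features(ft, labels,
                             selection_config(K1_grid = 1, K2_grid = 1,
                                              laplacian_k = 3),
                             n_electrodes = 4)
  expect_equal(sel_all$selected, seq_len(ncol(mat)))
  expect_equal(sort(sel_all$electrodes), paste0("E", 1:4))
  # identical inner accuracies resolve toward fewer electrodes/features
  flat <- make_ft(matrix(rep(c(0, 3), each = 8), 16, 8),
                  refs = rep(paste0("E", 1:2), each = 4))
  self <- select_features(flat, labels,
                          selection_config(K1_grid = c(0.5, 1),
                                           K2_grid = c(0.5, 1),
                                           laplacian_k = 3),
                          n_electrodes = 2)
  expect_equal(self$K1, 1L)
})

test_that("the two-class Gaussian model recovers means and floors variances", {
  set.seed(40)
  labels <- rep(c("healthy", "patient"), each = 10)
  X <- rbind(matrix(rnorm(10 * 3), 10), matrix(rnorm(10 * 3, mean = 2), 10))
  colnames(X) <- c("a", "b", "c")
  mod <- fit_two_model(X, labels)
  expect_equal(mod$mean_healthy, colMeans(X[1:10, ]), tolerance = 1e-12)
  expect_equal(mod$mean_patient, colMeans(X[11:20, ]), tolerance = 1e-12)
  # constant-within-class feature triggers the variance floor
  Xc <- cbind(X, d = rep(c(1, 2), each = 10))
  modc <- fit_two_model(Xc, labels)
  expect_equal(as.numeric(modc$var_healthy["d"]), 1e-12)
  expect_error(fit_two_model(X[c(1, 11, 12), ], labels[c(1, 11, 12)]),
               "2 training subjects")
})

test_that("classification is margin-consistent, tie-flagged and chi2-reported", {
  labels <- rep(c("healthy", "patient"), each = 4)
  X <- rbind(matrix(rnorm(8, mean = 0, sd = 1), 4),
             matrix(rnorm(8, mean = 4, sd = 1), 4))
  colnames(X) <- c("a", "b")
  mod <- fit_two_model(X, labels)
  at_h <- classify_subject(mod, setNames(mod$mean_healthy, c("a", "b")))
  expect_equal(at_h$label, "healthy")
  expect_gt(at_h$margin, 0)
  expect_equal(at_h$chi2_p, pchisq(2 * at_h$margin, 1, lower.tail = FALSE))
  # exactly equidistant subject: margin 0, tie to healthy, flagged
  mod_eq <- mod
  mod_eq$var_healthy <- mod_eq$var_patient <- c(a = 1, b = 1)
  mod_eq$mean_healthy <- c(a = -1, b = -1)
  mod_eq$mean_patient <- c(a = 1, b = 1)
  at_mid <- classify_subject(mod_eq, c(a = 0, b = 0))
  expect_equal(at_mid$margin, 0)
  expect_equal(at_mid$label, "healthy")
  expect_true(at_mid$tie)
  expect_error(classify_subject(mod, c(a = 1)), "missing feature")
  # margin doubles under feature duplication (independence assumption)
  X2 <- cbind(X, X); colnames(X2) <- c("a", "b", "a2", "b2")
  mod2 <- fit_two_model(X2, labels)
  x <- setNames(c(X[1, ], X[1, ]), colnames(X2))
  m1 <- classify_subject(mod, setNames(X[1, ], c("a", "b")))$margin
  m2 <- classify_subject(mod2, x)$margin
  expect_equal(m2, 2 * m1, tolerance = 1e-9)
})

test_that("within-class likelihood beats cross-class on separable data", {
  set.seed(55)
  labels <- rep(c("healthy", "patient"), each = 15)
  X <- rbind(matrix(rnorm(15 * 4), 15), matrix(rnorm(15 * 4, mean = 3), 15))
  colnames(X) <- paste0("f", 1:4)
  mod <- fit_two_model(X, labels)
  own_wins <- vapply(seq_len(30), function(i)
    classify_subject(mod, setNames(X[i, ], colnames(X)))$label == labels[i],
    logical(1))
  expect_gte(mean(own_wins), 0.95)
})
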