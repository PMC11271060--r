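# Selection pipeline: correlation filter, t-test filter, standardizer, and
# LASSO, plus the stage-nesting invariant.

test_that("correlation filter: identities, noise, and the frozen Pearson r", {
  ids <- sprintf("c%02d", 1:4)
  lesion <- data.frame(case_id = ids, f1 = c(1, 2, 3, 4),
                       f2 = c(1, 2, 3, 4), check.names = FALSE)
  node <- data.frame(case_id = ids, f1 = c(1, 2, 3, 5),
                     f2 = c(4, 3, 2, 1), check.names = FALSE)
  # r(f1) = 6.5 / sqrt(5 * 8.75) = 0.9827 > 0.9 -> retained
  kept <- cross_correlation_filter(lesion, node, threshold = 0.9)
  expect_true("f1" %in% kept)
  expect_equal(attr(kept, "r")[["f1"]], 6.5 / sqrt(5 * 8.75))
  # f2 is perfectly anticorrelated: retained with |r|, dropped signed
  expect_true("f2" %in% kept)
  kept_signed <- cross_correlation_filter(lesion, node, threshold = 0.9,
                                          use_abs = FALSE)
  expect_false("f2" %in% kept_signed)
  # identical columns (r = 1) retained; independent noise dropped
  set.seed(42)
  n <- 200
  les2 <- data.frame(case_id = sprintf("p%03d", 1:n), a = rnorm(n),
                     b = rnorm(n))
  nod2 <- data.frame(case_id = les2$case_id, a = les2$a, b = rnorm(n))
  kept2 <- cross_correlation_filter(les2, nod2)
  expect_identical(as.character(kept2), "a")
  expect_error(cross_correlation_filter(les2[1:2, ], nod2[1:2, ]),
               "at least 3")
  expect_error(cross_correlation_filter(les2, nod2[1:50, ]), "same positive")
})

test_that("correlation filter: 'any' mode and cross-tissue name pairing", {
  set.seed(43)
  n <- 100
  ids <- sprintf("p%03d", 1:n)
  x <- rnorm(n)
  lesion <- data.frame(case_id = ids, T2_tumor_original_firstorder_Mean = x,
                       check.names = FALSE)
  node <- data.frame(case_id = ids,
                     T2_node_original_firstorder_Mean = rnorm(n),
                     T2_node_original_firstorder_Median = x + rnorm(n, 0, 0.1),
                     check.names = FALSE)
  # paired mode sees only the same-named (Mean) column: dropped
  expect_length(cross_correlation_filter(lesion, node, mode = "paired"), 0)
  # any mode scans all node columns: the Median column correlates
  expect_length(cross_correlation_filter(lesion, node, mode = "any"), 1)
})

test_that("t-test filter: separation, degenerates, frozen toy statistic", {
  # {1,2,3} vs {4,5,6} equal-variance: t = -3.674, p = 0.0214
  X <- data.frame(case_id = sprintf("c%d", 1:6), f = c(1, 2, 3, 4, 5, 6))
  y <- c(1, 1, 1, 0, 0, 0)
  kept <- ttest_filter(X, y, var_equal = TRUE)
  expect_identical(as.character(kept), "f")
  expect_equal(attr(kept, "p")[["f"]],
               2 * pt(-abs(-3.674235), df = 4), tolerance = 1e-5)
  set.seed(44)
  n <- 100
  yy <- rep(c(0, 1), each = n / 2)
  X2 <- data.frame(case_id = sprintf("c%d", 1:n),
                   sig = yy + rnorm(n, 0, 0.05),   # label + tiny noise
                   flat = rep(1, n),               # constant in both groups
                   noise = rnorm(n))
  kept2 <- ttest_filter(X2, yy)
  expect_true("sig" %in% kept2)
  expect_false("flat" %in% kept2)
  expect_error(ttest_filter(X2, rep(1, n)), "both classes")
})

test_that("standardizer: train-only fitting and exact inversion", {
  set.seed(45)
  X <- data.frame(case_id = sprintf("c%d", 1:30),
                  a = rnorm(30, 5, 2), b = runif(30, -3, 9))
  std <- fit_standardizer(X)
  Z <- apply_standardizer(std, X)
  expect_equal(colMeans(as.matrix(Z[, -1])), c(a = 0, b = 0),
               tolerance = 1e-12)
  expect_equal(apply(as.matrix(Z[, -1]), 2, sd), c(a = 1, b = 1),
               tolerance = 1e-12)
  # validation rows use training parameters: shifted table not recentred
  Xv <- X; Xv$a <- Xv$a + 10
  Zv <- apply_standardizer(std, Xv)
  expect_gt(abs(mean(Zv$a)), 1)
  # round trip
  back <- apply_standardizer(std, Z, inverse = TRUE)
  expect_equal(back$a, X$a, tolerance = 1e-12)
  # zero-variance features dropped with a warning
  Xc <- X; Xc$c <- 3
  expect_warning(stdc <- fit_standardizer(Xc), "zero-variance")
  expect_false("c" %in% names(stdc$mean))
})

test_that("LASSO: shrinkage limits, soft-threshold oracle, monotone path", {
  set.seed(46)
  n <- 120
  y <- rep(c(0L, 1L), each = n / 2)
  X <- data.frame(case_id = sprintf("c%d", 1:n),
                  good = scale(y + rnorm(n, 0, 0.6))[, 1],
                  junk1 = rnorm(n), junk2 = rnorm(n))
  # penalty -> infinity: everything shrunk away
  res_inf <- lasso_select(X, y, lambda = 1e6)
  expect_length(res_inf$retained, 0)
  # linear-model variant on a single standardized feature matches the
  # closed-form soft-threshold solution (orthonormal-design identity)
  xs <- scale(X$good) * sqrt(n / (n - 1))  # population-sd scaling
  yc <- y - mean(y)
  rho <- mean(xs * yc)
  for (lam in c(0.02, 0.1)) {
    fit <- glmnet::glmnet(cbind(xs, 0), yc, family = "gaussian",
                          lambda = lam, standardize = FALSE,
                          intercept = FALSE)
    beta_hat <- as.numeric(coef(fit))[2]
    beta_oracle <- sign(rho) * max(0, abs(rho) - lam)
    expect_equal(beta_hat, beta_oracle, tolerance = 1e-3)
  }
  # retained-set size is non-increasing in the penalty
  sizes <- vapply(c(0.001, 0.05, 0.5), function(lam)
    length(lasso_select(X, y, lambda = lam)$retained), 0L)
  expect_true(all(diff(sizes) <= 0))
  # cross-validated selection keeps the informative feature
  res_cv <- lasso_select(X, y, seed = 9)
  expect_true("good" %in% res_cv$retained)
  expect_identical(res_cv$retained,
                   lasso_select(X, y, seed = 9)$retained)  # deterministic
})

test_that("staged selection nests and records its trace", {
  tb <- toy_tables(n_pos = 60, n_neg = 90, p = 50, p_inf = 6, seed = 47)
  y <- tb$labels$label
  std <- fit_standardizer(tb$lesion)
  Z <- apply_standardizer(std, tb$lesion)
  trace <- select_features(Z, y, node_pos = tb$node, seed = 3)
  expect_true(all(trace$stages$ttest %in% trace$stages$correlation))
  expect_true(all(trace$stages$lasso %in% trace$stages$ttest))
  inf <- attr(tb, "informative")
  # the correlation stage keeps essentially the informative set
  expect_gte(length(intersect(trace$stages$correlation, inf)), 5)
  expect_lte(length(setdiff(trace$stages$correlation, inf)), 3)
  # serialization
  jf <- tempfile(fileext = ".json"); cf <- tempfile(fileext = ".csv")
  write_selection_trace(trace, jf, cf)
  js <- jsonlite::read_json(jf)
  expect_named(js, c("stages", "weights", "thresholds"))
  expect_equal(nrow(read.csv(cf)), length(trace$weights))
})
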