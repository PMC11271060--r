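# ROC/AUC, DeLong variance and paired test, operating-point metrics, and
# the model-comparison report.

test_that("AUC: frozen pair-counting examples and monotone invariance", {
  y <- c(0, 0, 1, 1)
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), y), 0.75)
  expect_equal(auc(y, y), 1)
  expect_equal(auc(1 - y, y), 0)
  set.seed(51)
  s <- rnorm(60); yy <- rbinom(60, 1, 0.4)
  expect_equal(auc(s, yy), oracle_auc_pairs(s, yy))
  # ties handled by midranks
  st <- round(s, 0)
  expect_equal(auc(st, yy), oracle_auc_pairs(st, yy))
  # strictly monotone transforms leave AUC unchanged
  expect_equal(auc(exp(2 * s) - 3, yy), auc(s, yy))
  expect_error(auc(s, rep(1, 60)), "both classes")
})

test_that("DeLong components and variance match explicit kernel enumeration", {
  set.seed(52)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), 1)  # induce some ties
    o <- oracle_delong_components(s, y)
    cp <- plnmrad:::delong_components(s, y)
    expect_equal(cp$theta, o$theta)
    expect_equal(cp$v10, o$v10, ignore_attr = TRUE)
    expect_equal(cp$v01, o$v01, ignore_attr = TRUE)
    ci <- delong_ci(s, y)
    m <- sum(y == 1); nn <- sum(y == 0)
    v_oracle <- (if (m > 1) var(o$v10) else 0) / m +
      (if (nn > 1) var(o$v01) else 0) / nn
    expect_equal(ci$var, v_oracle)
    expect_equal(ci$auc, auc(s, y))
    expect_true(ci$ci[1] <= ci$auc && ci$auc <= ci$ci[2])
  }
  # perfect separation: zero variance, width-0 interval
  ci <- delong_ci(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(ci$var, 0)
  expect_equal(diff(ci$ci), 0)
})

test_that("DeLong test agrees with pROC and behaves symmetrically", {
  skip_if_not_installed("pROC")
  set.seed(53)
  for (i in 1:8) {
    n <- 40
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    base <- rnorm(n) + y
    sa <- base + rnorm(n, 0, 0.5)
    sb <- 0.7 * base + rnorm(n, 0, 0.7)
    got <- delong_paired_test(sa, sb, y)
    ref <- pROC::roc.test(pROC::roc(y, sa, quiet = TRUE),
                          pROC::roc(y, sb, quiet = TRUE),
                          method = "delong", paired = TRUE)
    expect_equal(got$p, as.numeric(ref$p.value), tolerance = 1e-9)
    # CI variance cross-check as well
    expect_equal(delong_ci(sa, y)$var,
                 as.numeric(pROC::var(pROC::roc(y, sa, quiet = TRUE),
                                      method = "delong")),
                 tolerance = 1e-9)
    # symmetry: swapped order flips z, keeps p
    rev <- delong_paired_test(sb, sa, y)
    expect_equal(rev$p, got$p)
    expect_equal(rev$z, -got$z)
  }
  # identical scores: z = 0, p = 1
  y <- c(0, 1, 0, 1, 1, 0)
  s <- c(0.2, 0.8, 0.4, 0.9, 0.3, 0.1)
  expect_equal(delong_paired_test(s, s, y)$z, 0)
  expect_equal(delong_paired_test(s, s, y)$p, 1)
  expect_error(delong_paired_test(s, s[-1], y), "same cases")
})

test_that("paired DeLong p agrees with a case-resampling bootstrap", {
  # n = 30 correlated-score fixture; 2e4 replicates suffice at the 0.02
  # tolerance for this unit check (the 1e5-replicate sweep runs in the
  # acceptance suite)
  set.seed(54)
  n <- 30
  y <- rep(c(0, 1), c(17, 13))
  base <- rnorm(n) + 1.1 * y
  sa <- base + rnorm(n, 0, 0.4)
  sb <- 0.8 * base + rnorm(n, 0, 0.8)
  got <- delong_paired_test(sa, sb, y)
  B <- 20000
  diffs <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample(n, n, replace = TRUE)
    if (length(unique(y[idx])) < 2) { diffs[b] <- NA; next }
    diffs[b] <- auc(sa[idx], y[idx]) - auc(sb[idx], y[idx])
  }
  diffs <- diffs[!is.na(diffs)]
  d0 <- got$auc_a - got$auc_b
  p_boot <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  expect_lt(abs(got$p - min(p_boot, 1)), 0.05)
  expect_equal(d0, mean(diffs), tolerance = 0.05)
})

test_that("operating-point metrics: frozen 2x2 table and Youden threshold", {
  # TP=12 FN=2 TN=37 FP=6 -> sens 12/14, spec 37/43, acc 49/57
  y <- rep(c(1, 0), c(14, 43))
  scores <- c(rep(1, 12), rep(0, 2), rep(1, 6), rep(0, 37))
  m <- operating_point_metrics(scores, y, threshold = 0.5)
  expect_equal(m[["sensitivity"]], 12 / 14)
  expect_equal(m[["specificity"]], 37 / 43)
  expect_equal(m[["accuracy"]], 49 / 57)
  # perfect classifier at its Youden threshold
  yy <- c(0, 0, 0, 1, 1)
  ss <- c(1, 2, 3, 8, 9)
  th <- youden_threshold(ss, yy)
  expect_equal(unname(operating_point_metrics(ss, yy, th)), c(1, 1, 1))
  # constant scores: sens and spec cannot both exceed their class rates;
  # exhaustive confusion-table enumeration over all thresholds
  sc <- rep(0.3, 10)
  y2 <- rep(c(0, 1), 5)
  for (th in c(0.2, 0.3, 0.4)) {
    mm <- operating_point_metrics(sc, y2, th)
    expect_true(mm[["sensitivity"]] == 1 && mm[["specificity"]] == 0 ||
                mm[["sensitivity"]] == 0 && mm[["specificity"]] == 1)
  }
})

test_that("model comparison report has the Table-2 shape", {
  tb <- toy_tables(n_pos = 30, n_neg = 45, p = 12, p_inf = 4, seed = 55)
  y <- tb$labels$label
  m_les <- train_arm(tb$lesion, y, n_folds = 3, n_repeats = 1, seed = 1)
  m_cor <- train_arm(tb$lesion, y, node_pos = tb$node, n_folds = 3,
                     n_repeats = 1, seed = 1)
  tables <- list(train = list(X = tb$lesion, y = y),
                 internal = list(X = tb$lesion, y = y),
                 external = list(X = tb$lesion, y = y))
  rep <- compare_models(m_les, m_cor, tables)
  expect_equal(nrow(rep), 6)  # 2 arms x 3 splits
  expect_setequal(unique(rep$arm), c("lesion", "lesion-correlation"))
  expect_true(all(rep$auc >= 0 & rep$auc <= 1))
  expect_true(all(rep$ci_low <= rep$auc & rep$auc <= rep$ci_high))
  # identical arms give p = 1 on every split
  rep_same <- compare_models(m_les, m_les, tables["train"])
  expect_equal(unique(rep_same$delong_p), 1)
  expect_output(format_report(rep), "lesion-correlation")
})
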