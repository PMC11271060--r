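# ROC evaluation: Mann-Whitney AUC with midranks, DeLong
# structural-component variance and confidence intervals, the paired DeLong
# test for two correlated AUCs, operating-point metrics, and the two-arm
# comparison report.

check_scores_labels <- function(scores, y) {
  y <- as.integer(y)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  if (any(!y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L)
    stop("both classes must be present")
  y
}

#' Area under the ROC curve
#'
#' Mann-Whitney estimator with midranks for ties: the probability that a
#' random positive case scores above a random negative case (ties count
#' one-half). Invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric decision scores (larger = more positive-like).
#' @param y 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
auc <- function(scores, y) {
  y <- check_scores_labels(scores, y)
  m <- sum(y == 1L)
  n <- sum(y == 0L)
  r <- rank(scores)  # midranks
  (sum(r[y == 1L]) - m * (m + 1) / 2) / (m * n)
}

# DeLong structural components: V10 (per positive) and V01 (per negative),
# via midranks.
delong_components <- function(scores, y) {
  pos <- scores[y == 1L]
  neg <- scores[y == 0L]
  m <- length(pos)
  n <- length(neg)
  r_all <- rank(c(pos, neg))
  r_pos <- rank(pos)
  r_neg <- rank(neg)
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  theta <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(theta = theta, v10 = v10, v01 = v01, m = m, n = n)
}

var_or_zero <- function(x) if (length(x) > 1L) stats::var(x) else 0

#' AUC with DeLong variance and confidence interval
#'
#' Estimates the AUC and its sampling variance from the DeLong structural
#' components (midranks throughout), with a normal-approximation confidence
#' interval on the AUC scale, truncated to `[0, 1]`. Perfect separation
#' gives zero variance and a width-0 interval.
#'
#' @param scores numeric decision scores.
#' @param y 0/1 labels (each class with at least 2 members for a nonzero
#'   variance estimate).
#' @param level confidence level (default 0.95).
#' @return List with `auc`, `var`, `ci` (length 2), and `level`.
#' @export
delong_ci <- function(scores, y, level = 0.95) {
  y <- check_scores_labels(scores, y)
  cp <- delong_components(scores, y)
  v <- var_or_zero(cp$v10) / cp$m + var_or_zero(cp$v01) / cp$n
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(v)
  list(auc = cp$theta, var = v,
       ci = c(max(0, cp$theta - half), min(1, cp$theta + half)),
       level = level)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors over the same cases using the
#' DeLong covariance of the paired structural components; two-sided normal
#' test. Swapping the two models negates `z` and leaves `p` unchanged.
#' Identical scores give `z = 0`, `p = 1`.
#'
#' @param scores_a,scores_b decision scores of the two models on the same
#'   cases, same order.
#' @param y 0/1 labels.
#' @return List with `auc_a`, `auc_b`, `var_diff`, `z`, and two-sided `p`.
#' @export
delong_paired_test <- function(scores_a, scores_b, y) {
  if (length(scores_a) != length(scores_b))
    stop("the two score vectors must cover the same cases")
  y <- check_scores_labels(scores_a, y)
  ca <- delong_components(scores_a, y)
  cb <- delong_components(scores_b, y)
  cov_or_zero <- function(a, b) if (length(a) > 1L) stats::cov(a, b) else 0
  s10 <- var_or_zero(ca$v10) + var_or_zero(cb$v10) -
    2 * cov_or_zero(ca$v10, cb$v10)
  s01 <- var_or_zero(ca$v01) + var_or_zero(cb$v01) -
    2 * cov_or_zero(ca$v01, cb$v01)
  v <- s10 / ca$m + s01 / ca$n
  d <- ca$theta - cb$theta
  z <- if (v > 0) d / sqrt(v) else if (d == 0) 0 else sign(d) * Inf
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))
  list(auc_a = ca$theta, auc_b = cb$theta, var_diff = v, z = z, p = p)
}

#' Confusion-matrix metrics at a fixed threshold
#'
#' Cases with `score >= threshold` are called positive.
#'
#' @param scores numeric decision scores.
#' @param y 0/1 labels.
#' @param threshold decision threshold.
#' @return Named vector: accuracy, sensitivity, specificity.
#' @export
operating_point_metrics <- function(scores, y, threshold) {
  y <- as.integer(y)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  tn <- sum(pred == 0L & y == 0L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  c(accuracy = (tp + tn) / length(y),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Youden-optimal threshold
#'
#' The candidate threshold (midpoint between adjacent distinct scores)
#' maximizing Youden's J = sensitivity + specificity - 1; ties broken toward
#' the higher threshold.
#'
#' @param scores numeric decision scores.
#' @param y 0/1 labels.
#' @return A single threshold value.
#' @export
youden_threshold <- function(scores, y) {
  y <- check_scores_labels(scores, y)
  s <- sort(unique(scores))
  cand <- if (length(s) > 1L) (s[-1] + s[-length(s)]) / 2 else s
  cand <- c(min(s) - 1, cand)
  j <- vapply(cand, function(th) {
    m <- operating_point_metrics(scores, y, th)
    m[["sensitivity"]] + m[["specificity"]] - 1
  }, 0)
  cand[max(which(j == max(j)))]
}

#' Compare two trained models across cohort splits
#'
#' Builds the per-split performance report of the two model arms: AUC with
#' DeLong confidence interval, accuracy/sensitivity/specificity at each
#' model's training-fixed threshold, and the paired DeLong p-value between
#' the arms on the same cases. One row per (split, arm).
#'
#' @param model_a,model_b [train_svm_cv()] models (e.g. the "lesion" and
#'   "lesion-correlation" arms).
#' @param tables named list of splits; each element a list with `X` (lesion
#'   feature table) and `y` (0/1 labels).
#' @param level confidence level for the AUC interval.
#' @return Data frame with columns split, arm, auc, ci_low, ci_high,
#'   accuracy, sensitivity, specificity, delong_p.
#' @export
compare_models <- function(model_a, model_b, tables, level = 0.95) {
  rows <- list()
  for (split in names(tables)) {
    tb <- tables[[split]]
    if (is.null(tb$X) || is.null(tb$y)) stop("missing split data: ", split)
    sa <- predict_scores(model_a, tb$X)
    sb <- predict_scores(model_b, tb$X)
    dl <- delong_paired_test(sa, sb, tb$y)
    for (arm in c("a", "b")) {
      mod <- if (arm == "a") model_a else model_b
      sc <- if (arm == "a") sa else sb
      ci <- delong_ci(sc, tb$y, level = level)
      met <- operating_point_metrics(sc, tb$y, mod$threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        split = split, arm = mod$arm, auc = ci$auc,
        ci_low = ci$ci[1], ci_high = ci$ci[2],
        accuracy = met[["accuracy"]], sensitivity = met[["sensitivity"]],
        specificity = met[["specificity"]], delong_p = dl$p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a comparison report as aligned text
#'
#' @param report data frame from [compare_models()].
#' @return Character vector of lines, invisibly; also printed.
#' @export
format_report <- function(report) {
  lines <- c(sprintf("%-10s %-18s %6s  [%s]  %6s %6s %6s  %8s",
                     "split", "arm", "AUC", "95% CI", "acc", "sens",
                     "spec", "DeLong p"))
  for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    lines <- c(lines, sprintf(
      "%-10s %-18s %6.4f  [%6.4f-%6.4f]  %6.4f %6.4f %6.4f  %8.4f",
      r$split, r$arm, r$auc, r$ci_low, r$ci_high, r$accuracy,
      r$sensitivity, r$specificity, r$delong_p))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
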