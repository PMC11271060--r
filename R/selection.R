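# Three-stage feature selection: cross-tissue Pearson-correlation filter
# (the pipeline's distinctive step) -> two-sample t test -> LASSO, plus the
# train-fitted standardizer. Retained sets are nested across stages.

feature_matrix <- function(table) {
  stopifnot(is.data.frame(table), "case_id" %in% names(table))
  m <- as.matrix(table[, setdiff(names(table), "case_id"), drop = FALSE])
  rownames(m) <- table$case_id
  storage.mode(m) <- "double"
  m
}

# Tissue-agnostic canonical name: extracted features differ between tissues
# only in the "<tissue>" name component ("tumor" vs "node"); simulated
# tables use identical names in both tissues.
strip_tissue <- function(nm) {
  nm <- sub("^(T2|ADC)_(tumor|node)_", "\\1_", nm)
  nm
}

#' Cross-tissue Pearson-correlation feature filter
#'
#' The correlation-guided selection step: a primary-lesion feature is
#' retained only if it correlates strongly (|r| > `threshold`, strict) with
#' metastatic-node features across PLNM-positive cases. In `"paired"` mode
#' (default) each lesion feature is compared with its same-named node
#' feature (names matched after dropping the tissue component); in `"any"`
#' mode the maximum |r| over all node features is used. Absolute correlation
#' is the default (anticorrelation is equally informative); set
#' `use_abs = FALSE` for the signed-only rule.
#'
#' @param lesion_pos lesion feature table (data frame with `case_id`) for
#'   PLNM-positive cases.
#' @param node_pos node feature table for the same cases, same order not
#'   required (rows are matched by `case_id`).
#' @param threshold correlation threshold in (0, 1]; default 0.9.
#' @param mode `"paired"` or `"any"`.
#' @param use_abs use |r| (default) instead of signed r.
#' @return Character vector of retained lesion feature names, with the
#'   per-feature correlations attached as `attr(, "r")`.
#' @export
cross_correlation_filter <- function(lesion_pos, node_pos, threshold = 0.9,
                                     mode = c("paired", "any"),
                                     use_abs = TRUE) {
  mode <- match.arg(mode)
  assert_scalar_number(threshold, "threshold", lower = 1e-12, upper = 1)
  X <- feature_matrix(lesion_pos)
  Y <- feature_matrix(node_pos)
  if (!setequal(rownames(X), rownames(Y)))
    stop("lesion and node tables must be indexed by the same positive cases")
  Y <- Y[rownames(X), , drop = FALSE]
  if (nrow(X) < 3L)
    stop("need at least 3 positive cases to estimate correlations")
  score <- function(r) if (use_abs) abs(r) else r
  if (mode == "paired") {
    key_x <- strip_tissue(colnames(X))
    key_y <- strip_tissue(colnames(Y))
    j <- match(key_x, key_y)
    if (anyNA(j))
      stop("paired mode: no same-named node feature for: ",
           paste(utils::head(colnames(X)[is.na(j)], 3), collapse = ", "))
    r <- vapply(seq_len(ncol(X)), function(k) {
      suppressWarnings(stats::cor(X[, k], Y[, j[k]]))
    }, 0)
    r[is.na(r)] <- 0  # zero-variance columns cannot pass
    keep <- score(r) > threshold
    out <- colnames(X)[keep]
    attr(out, "r") <- stats::setNames(r, colnames(X))
  } else {
    R <- suppressWarnings(stats::cor(X, Y))
    R[is.na(R)] <- 0
    best <- apply(score(R), 1, max)
    keep <- best > threshold
    out <- colnames(X)[keep]
    attr(out, "r") <- best
  }
  out
}

#' Per-feature two-sample t-test filter
#'
#' Retains features whose two-sample t test between PLNM-positive and
#' negative cases gives p < `alpha`. Welch's variant by default; set
#' `var_equal = TRUE` for the pooled-variance test. Features that are
#' constant within both groups have an undefined statistic and are dropped.
#'
#' @param X feature table (data frame with `case_id`) or numeric matrix.
#' @param y 0/1 labels, one per row.
#' @param alpha significance level (default 0.05).
#' @param var_equal pooled-variance t test instead of Welch.
#' @return Character vector of retained feature names with p-values attached
#'   as `attr(, "p")`.
#' @export
ttest_filter <- function(X, y, alpha = 0.05, var_equal = FALSE) {
  M <- if (is.data.frame(X)) feature_matrix(X) else X
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (length(y) != nrow(M)) stop("length(y) must equal nrow(X)")
  p <- vapply(seq_len(ncol(M)), function(k) {
    a <- M[y == 1L, k]; b <- M[y == 0L, k]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) return(NA_real_)
    tryCatch(stats::t.test(a, b, var.equal = var_equal)$p.value,
             error = function(e) NA_real_)
  }, 0)
  keep <- !is.na(p) & p < alpha
  out <- colnames(M)[keep]
  attr(out, "p") <- stats::setNames(p, colnames(M))
  out
}

#' Fit / apply a feature standardizer
#'
#' Learns per-feature mean and standard deviation from training rows;
#' `apply_standardizer()` transforms any table with those training
#' parameters (validation rows are never refit). Zero-variance features are
#' dropped with a warning.
#'
#' @param X_train training feature table (data frame with `case_id`) or
#'   matrix.
#' @return A `standardizer` with fields `mean` and `sd`.
#' @export
fit_standardizer <- function(X_train) {
  M <- if (is.data.frame(X_train)) feature_matrix(X_train) else X_train
  mu <- colMeans(M)
  sdv <- apply(M, 2, stats::sd)
  drop <- sdv <= 0 | !is.finite(sdv)
  if (any(drop)) {
    warning(sum(drop), " zero-variance feature(s) dropped by standardizer")
    mu <- mu[!drop]; sdv <- sdv[!drop]
  }
  structure(list(mean = mu, sd = sdv), class = "standardizer")
}

#' @rdname fit_standardizer
#' @param std a fitted `standardizer`.
#' @param X table or matrix to transform; must contain the fitted features.
#' @param inverse undo the transform instead.
#' @export
apply_standardizer <- function(std, X, inverse = FALSE) {
  stopifnot(inherits(std, "standardizer"))
  is_df <- is.data.frame(X)
  M <- if (is_df) feature_matrix(X) else X
  missing <- setdiff(names(std$mean), colnames(M))
  if (length(missing))
    stop("table lacks standardized features: ",
         paste(utils::head(missing, 3), collapse = ", "))
  M <- M[, names(std$mean), drop = FALSE]
  Z <- if (inverse) sweep(sweep(M, 2, std$sd, `*`), 2, std$mean, `+`)
       else sweep(sweep(M, 2, std$mean, `-`), 2, std$sd, `/`)
  if (is_df) data.frame(case_id = X$case_id, Z, check.names = FALSE)
  else Z
}

# Stratified fold assignment (deterministic given the RNG state).
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' LASSO feature selection with repeated cross-validation
#'
#' L1-penalized logistic regression on standardized features; the penalty is
#' chosen to minimize binomial deviance averaged over `n_repeats` rounds of
#' stratified `n_folds`-fold cross-validation (ties broken toward the
#' sparser model, i.e. the larger penalty). Features with nonzero
#' coefficients at the chosen penalty are retained.
#'
#' @param X standardized feature table (data frame with `case_id`) or matrix.
#' @param y 0/1 labels.
#' @param n_folds,n_repeats cross-validation design (defaults 5 and 5).
#' @param seed RNG seed for fold assignment.
#' @param lambda optional fixed penalty (skips cross-validation).
#' @return List with `retained` (feature names), `weights` (named nonzero
#'   coefficients), `lambda`, and `intercept`.
#' @export
lasso_select <- function(X, y, n_folds = 5, n_repeats = 5, seed = 1,
                         lambda = NULL) {
  M <- if (is.data.frame(X)) feature_matrix(X) else X
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (ncol(M) < 2L) {
    # glmnet requires >= 2 columns; duplicate-free padding with a zero column
    M <- cbind(M, `.pad.` = 0)
  }
  # glmnet warns when a class has < 8 members; expected for small cohorts
  quiet_glmnet <- function(expr) withCallingHandlers(expr,
    warning = function(w) {
      if (grepl("fewer than 8 +observations", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (is.null(lambda)) {
    base_fit <- quiet_glmnet(
      glmnet::glmnet(M, y, family = "binomial", standardize = FALSE))
    lam_seq <- base_fit$lambda
    cvm <- matrix(0, length(lam_seq), n_repeats)
    withr::with_seed(seed, {
      for (r in seq_len(n_repeats)) {
        foldid <- stratified_folds(y, n_folds)
        cv <- quiet_glmnet(
          glmnet::cv.glmnet(M, y, family = "binomial", foldid = foldid,
                            lambda = lam_seq, type.measure = "deviance",
                            standardize = FALSE))
        cvm[, r] <- cv$cvm[match(lam_seq, cv$lambda)]
      }
    })
    mean_cvm <- rowMeans(cvm, na.rm = TRUE)
    best <- which(mean_cvm <= min(mean_cvm, na.rm = TRUE) + 1e-12)
    lambda <- max(lam_seq[best])  # sparser model on ties
    fit <- base_fit
  } else {
    fit <- quiet_glmnet(
      glmnet::glmnet(M, y, family = "binomial", standardize = FALSE))
  }
  cf <- as.matrix(stats::coef(fit, s = lambda, exact = FALSE))
  w <- cf[-1, 1]
  w <- w[w != 0 & names(w) != ".pad."]
  list(retained = names(w), weights = w, lambda = lambda,
       intercept = cf[1, 1])
}

#' Run the staged selection pathway and record its trace
#'
#' Applies, in order: the cross-tissue correlation filter (when node
#' features are supplied - the "lesion-correlation" pathway), the t-test
#' filter, and LASSO; features surviving each stage are recorded. The
#' retained sets are nested by construction.
#'
#' @param lesion standardized lesion table (data frame with `case_id`).
#' @param y 0/1 labels for `lesion` rows.
#' @param node_pos standardized node table for positive cases, or `NULL`
#'   for the plain lesion pathway.
#' @param threshold,mode,use_abs correlation-filter parameters.
#' @param alpha t-test level.
#' @param n_folds,n_repeats,seed LASSO cross-validation parameters.
#' @return A `selection_trace`: list of per-stage retained names, LASSO
#'   weights, and the thresholds used.
#' @export
select_features <- function(lesion, y, node_pos = NULL, threshold = 0.9,
                            mode = "paired", use_abs = TRUE, alpha = 0.05,
                            n_folds = 5, n_repeats = 5, seed = 1) {
  stages <- list()
  X <- lesion
  all_names <- setdiff(names(lesion), "case_id")
  if (!is.null(node_pos)) {
    pos_ids <- lesion$case_id[y == 1L]
    lesion_pos <- lesion[match(pos_ids, lesion$case_id), , drop = FALSE]
    node_pos <- node_pos[node_pos$case_id %in% pos_ids, , drop = FALSE]
    kept <- cross_correlation_filter(lesion_pos, node_pos,
                                     threshold = threshold, mode = mode,
                                     use_abs = use_abs)
    stages$correlation <- as.character(kept)
    X <- X[, c("case_id", stages$correlation), drop = FALSE]
  } else {
    stages$correlation <- NULL
  }
  kept_t <- ttest_filter(X, y, alpha = alpha)
  stages$ttest <- as.character(kept_t)
  Xt <- X[, c("case_id", stages$ttest), drop = FALSE]
  if (length(stages$ttest) == 0L)
    stop("no features survive the t-test filter")
  las <- lasso_select(Xt, y, n_folds = n_folds, n_repeats = n_repeats,
                      seed = seed)
  stages$lasso <- las$retained
  structure(list(stages = stages, weights = las$weights,
                 lambda = las$lambda, intercept = las$intercept,
                 thresholds = list(correlation = if (is.null(node_pos)) NA
                                   else threshold,
                                   alpha = alpha),
                 n_input = length(all_names)),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace>\n")
  cat("  input features:", x$n_input, "\n")
  for (s in names(x$stages))
    cat(sprintf("  after %-11s %d retained\n", paste0(s, ":"),
                length(x$stages[[s]])))
  invisible(x)
}

#' Serialize a selection trace to JSON / weights to CSV
#'
#' @param trace a `selection_trace`.
#' @param json_path,weights_csv output paths (either may be `NULL`).
#' @return `invisible(NULL)`.
#' @export
write_selection_trace <- function(trace, json_path = NULL,
                                  weights_csv = NULL) {
  stopifnot(inherits(trace, "selection_trace"))
  if (!is.null(json_path))
    jsonlite::write_json(list(stages = trace$stages,
                              weights = as.list(trace$weights),
                              thresholds = trace$thresholds),
                         json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(weights_csv))
    utils::write.csv(data.frame(feature = names(trace$weights),
                                weight = unname(trace$weights)),
                     weights_csv, row.names = FALSE)
  invisible(NULL)
}
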