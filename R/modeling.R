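# Class rebalancing (SMOTE), SVM training with repeated stratified
# cross-validation, and scoring. SMOTE is applied inside each training fold
# only (never to validation folds), and again to the full training set for
# the final refit; the decision threshold is fixed from training data only.

#' SMOTE minority oversampling
#'
#' Balances the classes by synthesizing minority-class rows: each synthetic
#' row is a convex combination `x + u * (nn - x)`, `u ~ U(0, 1)`, of a
#' random minority row `x` and one of its `k` nearest minority neighbours
#' `nn` (Euclidean distance). Majority rows are untouched.
#'
#' @param X numeric matrix or feature table (data frame with `case_id`).
#' @param y 0/1 labels, one per row.
#' @param k number of nearest neighbours (capped at minority size - 1).
#' @param seed RNG seed.
#' @return List with `X` (matrix) and `y`, classes balanced; synthetic rows
#'   are appended after the originals.
#' @export
smote_oversample <- function(X, y, k = 5, seed = 1) {
  M <- if (is.data.frame(X)) feature_matrix(X) else as.matrix(X)
  y <- as.integer(y)
  tab <- table(factor(y, levels = c(0L, 1L)))
  minority <- as.integer(names(tab)[which.min(tab)])
  n_extra <- abs(tab[[1]] - tab[[2]])
  if (n_extra == 0L) return(list(X = M, y = y))
  idx_min <- which(y == minority)
  if (length(idx_min) < 2L)
    stop("SMOTE requires a minority class of at least 2 members")
  Mm <- M[idx_min, , drop = FALSE]
  k <- min(k, nrow(Mm) - 1L)
  D <- as.matrix(stats::dist(Mm))
  diag(D) <- Inf
  nn_idx <- t(matrix(apply(D, 1, function(row) order(row)[seq_len(k)]),
                     nrow = k))
  synth <- withr::with_seed(seed, {
    base <- sample(nrow(Mm), n_extra, replace = TRUE)
    pick <- nn_idx[cbind(base, sample(k, n_extra, replace = TRUE))]
    u <- stats::runif(n_extra)
    Mm[base, , drop = FALSE] +
      u * (Mm[pick, , drop = FALSE] - Mm[base, , drop = FALSE])
  })
  list(X = rbind(M, synth), y = c(y, rep(minority, n_extra)))
}

#' Default SVM hyperparameter grid
#'
#' RBF kernel with cost `C` in {0.1, 1, 10, 100} and gamma equal to the
#' scale heuristic `1 / (n_features * var(X))` times {0.1, 1, 10}.
#'
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param cost candidate costs.
#' @param gamma_mult multipliers of the scale-heuristic gamma (ignored for
#'   the linear kernel).
#' @return A `svm_grid` list.
#' @export
default_svm_grid <- function(kernel = c("radial", "linear"),
                             cost = c(0.1, 1, 10, 100),
                             gamma_mult = c(0.1, 1, 10)) {
  kernel <- match.arg(kernel)
  structure(list(kernel = kernel, cost = cost, gamma_mult = gamma_mult),
            class = "svm_grid")
}

# Fit an SVM and return oriented decision scores for new data.
svm_fit <- function(X, y, kernel, cost, gamma) {
  e1071::svm(x = X, y = factor(y, levels = c(0L, 1L)), kernel = kernel,
             cost = cost, gamma = gamma, scale = FALSE)
}

svm_scores <- function(fit, X) {
  dv <- attr(stats::predict(fit, X, decision.values = TRUE),
             "decision.values")
  # orientation: a positive decision value favours the class named first
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  s <- as.numeric(dv[, 1])
  if (first == "0") s <- -s
  s
}

#' Train an SVM with repeated stratified cross-validation
#'
#' Selects the hyperparameters maximizing mean held-out AUC over
#' `n_repeats` rounds of stratified `n_folds`-fold cross-validation, with
#' SMOTE applied to the training portion of each fold only; refits on the
#' full training set (SMOTE-rebalanced) with the winning parameters, and
#' fixes the decision threshold by Youden's J on the training ROC (original
#' training rows). Ties on the CV curve break toward the smaller cost, then
#' the smaller gamma. Fully deterministic given `seed`.
#'
#' @param X standardized selected-feature table (data frame with `case_id`)
#'   or matrix.
#' @param y 0/1 labels.
#' @param n_folds,n_repeats cross-validation design (defaults 5, 5).
#' @param grid a [default_svm_grid()].
#' @param seed master seed for folds and SMOTE.
#' @param smote apply SMOTE rebalancing (default TRUE).
#' @param arm label stored on the model (e.g. `"lesion"`).
#' @return A `trained_model`; see also [predict_scores()].
#' @export
train_svm_cv <- function(X, y, n_folds = 5, n_repeats = 5,
                         grid = default_svm_grid(), seed = 1, smote = TRUE,
                         arm = "model") {
  M <- if (is.data.frame(X)) feature_matrix(X) else as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  gamma0 <- 1 / (ncol(M) * max(stats::var(as.vector(M)), 1e-12))
  combos <- if (grid$kernel == "linear")
    data.frame(cost = grid$cost, gamma = gamma0)
  else expand.grid(gamma = gamma0 * grid$gamma_mult, cost = grid$cost)[, 2:1]
  fold_auc <- array(NA_real_, c(nrow(combos), n_repeats, n_folds))
  withr::with_seed(derive_seed(seed, 0L), {
    for (r in seq_len(n_repeats)) {
      folds <- stratified_folds(y, n_folds)
      for (f in seq_len(n_folds)) {
        tr <- folds != f
        if (length(unique(y[!tr])) < 2L) next
        dat <- if (smote)
          smote_oversample(M[tr, , drop = FALSE], y[tr],
                           seed = derive_seed(seed, r * 100L + f))
        else list(X = M[tr, , drop = FALSE], y = y[tr])
        for (g in seq_len(nrow(combos))) {
          fit <- svm_fit(dat$X, dat$y, grid$kernel, combos$cost[g],
                         combos$gamma[g])
          sc <- svm_scores(fit, M[!tr, , drop = FALSE])
          fold_auc[g, r, f] <- auc(sc, y[!tr])
        }
      }
    }
  })
  mean_auc <- apply(fold_auc, 1, mean, na.rm = TRUE)
  best <- which(mean_auc >= max(mean_auc) - 1e-12)[1]
  dat <- if (smote) smote_oversample(M, y, seed = derive_seed(seed, 1L))
         else list(X = M, y = y)
  fit <- svm_fit(dat$X, dat$y, grid$kernel, combos$cost[best],
                 combos$gamma[best])
  train_scores <- svm_scores(fit, M)
  structure(list(arm = arm, fit = fit, features = colnames(M),
                 kernel = grid$kernel, cost = combos$cost[best],
                 gamma = combos$gamma[best],
                 threshold = youden_threshold(train_scores, y),
                 cv_auc = mean_auc[best],
                 cv_fold_auc = fold_auc[best, , ],
                 standardizer = NULL, trace = NULL, seed = seed),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "<trained_model> arm '%s': %s SVM (C=%g, gamma=%.4g), %d features, CV AUC %.3f\n",
    x$arm, x$kernel, x$cost, x$gamma, length(x$features), x$cv_auc))
  invisible(x)
}

#' Score cases with a trained model
#'
#' Applies the model's stored standardizer (if any), selects its retained
#' features by name (column order of `X` is irrelevant), and returns the
#' oriented SVM decision score per case (larger = more PLNM-like).
#'
#' @param model a `trained_model` from [train_svm_cv()] or [train_arm()].
#' @param X feature table (data frame with `case_id`) or matrix containing
#'   the model's features.
#' @return Numeric score vector, one per row of `X`.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "trained_model"))
  M <- if (is.data.frame(X)) feature_matrix(X) else as.matrix(X)
  if (!is.null(model$standardizer))
    M <- apply_standardizer(model$standardizer, M)
  missing <- setdiff(model$features, colnames(M))
  if (length(missing))
    stop("table lacks model features: ", paste(missing, collapse = ", "))
  svm_scores(model$fit, M[, model$features, drop = FALSE])
}

#' Train one model arm end to end
#'
#' Full training pathway for one arm: fit the standardizer on training rows,
#' run the staged selection ([select_features()]; the cross-tissue
#' correlation filter participates iff `node_pos` is given, yielding the
#' "lesion-correlation" arm, otherwise the "lesion" arm), and train the
#' SMOTE + SVM classifier on the selected standardized features. Every
#' fitted parameter (standardizer, retained sets, hyperparameters,
#' threshold) derives from the training rows only.
#'
#' @param lesion lesion feature table for training cases (data frame with
#'   `case_id`).
#' @param y 0/1 training labels.
#' @param node_pos node feature table for PLNM-positive training cases, or
#'   `NULL` for the plain lesion arm.
#' @param threshold,mode,use_abs,alpha selection parameters (see
#'   [select_features()]).
#' @param n_folds,n_repeats cross-validation design.
#' @param grid a [default_svm_grid()].
#' @param seed master seed.
#' @return A `trained_model` with the selection trace attached.
#' @export
train_arm <- function(lesion, y, node_pos = NULL, threshold = 0.9,
                      mode = "paired", use_abs = TRUE, alpha = 0.05,
                      n_folds = 5, n_repeats = 5, grid = default_svm_grid(),
                      seed = 1) {
  std <- fit_standardizer(lesion)
  Z <- apply_standardizer(std, lesion)
  trace <- select_features(Z, y, node_pos = node_pos, threshold = threshold,
                           mode = mode, use_abs = use_abs, alpha = alpha,
                           n_folds = n_folds, n_repeats = n_repeats,
                           seed = derive_seed(seed, 2L))
  if (length(trace$stages$lasso) == 0L)
    stop("LASSO retained no features; cannot train the arm")
  Xs <- Z[, c("case_id", trace$stages$lasso), drop = FALSE]
  model <- train_svm_cv(Xs, y, n_folds = n_folds, n_repeats = n_repeats,
                        grid = grid, seed = derive_seed(seed, 3L),
                        arm = if (is.null(node_pos)) "lesion"
                              else "lesion-correlation")
  model$standardizer <- std
  model$trace <- trace
  model
}
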