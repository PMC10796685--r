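# Cross-validated linear ridge decoder: one 20-ms bin of firing rates in,
# four velocity components (right x/y, left x/y) out.

#' Train a ridge-regression velocity decoder
#'
#' Closed-form ridge with intercept; the penalty is selected from `alpha_grid`
#' by k-fold cross-validation, maximizing the mean held-out Pearson r across
#' output dimensions. Folds are stratified by `groups` (e.g. movement context)
#' so every fold balances unimanual-right and unimanual-left time steps.
#'
#' @param features bins x channels matrix.
#' @param targets bins x 4 matrix of velocity targets
#'   (`v_rx`, `v_ry`, `v_lx`, `v_ly`).
#' @param alpha_grid Positive ridge penalties to sweep.
#' @param k Number of cross-validation folds.
#' @param groups Optional per-bin stratification labels.
#' @param seed RNG seed for fold assignment.
#' @return A `bci_ridge` model with fields `W` (channels x 4), `intercept`,
#'   `alpha`, `cv_r` (per-output held-out r at the chosen penalty).
#' @export
train_ridge <- function(features, targets, alpha_grid = 10^seq(-2, 5, by = 1),
                        k = 5, groups = NULL, seed = 1L) {
  features <- as.matrix(features); targets <- as.matrix(targets)
  stopifnot(nrow(features) == nrow(targets))
  if (length(alpha_grid) == 0) stop("`alpha_grid` must be non-empty")
  folds <- stratified_folds(nrow(features), k, groups, seed)

  cv_pred <- array(NA_real_, c(nrow(features), ncol(targets), length(alpha_grid)))
  for (f in seq_len(k)) {
    te <- which(folds == f); tr <- which(folds != f)
    fits <- ridge_path(features[tr, , drop = FALSE], targets[tr, , drop = FALSE],
                       alpha_grid)
    for (a in seq_along(alpha_grid)) {
      cv_pred[te, , a] <- predict_linear(fits[[a]], features[te, , drop = FALSE])
    }
  }
  score <- vapply(seq_along(alpha_grid), function(a) {
    mean(vapply(seq_len(ncol(targets)), function(j)
      safe_cor(cv_pred[, j, a], targets[, j]), numeric(1)), na.rm = TRUE)
  }, numeric(1))
  best <- which.max(score)
  fit <- ridge_path(features, targets, alpha_grid[best])[[1]]
  cv_r <- vapply(seq_len(ncol(targets)), function(j)
    safe_cor(cv_pred[, j, best], targets[, j]), numeric(1))
  structure(list(W = fit$W, intercept = fit$intercept,
                 alpha = alpha_grid[best], alpha_grid = alpha_grid,
                 grid_score = score, cv_r = cv_r, folds = folds),
            class = "bci_ridge")
}

# Fit ridge for several penalties reusing one eigendecomposition of X'X.
ridge_path <- function(X, Y, alphas) {
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  ed <- eigen(crossprod(Xc), symmetric = TRUE)
  XtY <- crossprod(Xc, Yc)
  VtXtY <- crossprod(ed$vectors, XtY)
  lapply(alphas, function(a) {
    W <- ed$vectors %*% (VtXtY / (pmax(ed$values, 0) + a))
    list(W = W, intercept = ym - drop(xm %*% W))
  })
}

predict_linear <- function(fit, X) {
  sweep(X %*% fit$W, 2, fit$intercept, `+`)
}

#' @export
predict.bci_ridge <- function(object, newdata, ...) {
  predict_linear(object, as.matrix(newdata))
}

# Fold assignment stratified by a grouping label: units are ordered by
# (shuffled) stratum and dealt to folds cyclically with a random starting
# fold, so fold sizes are globally balanced (+/- 1) and every stratum is
# spread across folds even when strata are tiny.
stratified_folds <- function(n, k, groups = NULL, seed = 1L) {
  if (is.null(groups)) groups <- rep(1L, n)
  folds <- integer(n)
  with_seed(child_seed(seed, "folds"), {
    resample <- function(x) x[sample.int(length(x))]
    strata <- resample(unique(groups))
    ord <- unlist(lapply(strata, function(g) resample(which(groups == g))))
    start <- sample.int(k, 1)
    folds[ord] <- rep_len((seq_len(n) + start) %% k + 1L, n)
  })
  folds
}

#' Offline decoding performance
#'
#' Runs a decoder over a feature matrix and reports the per-dimension Pearson
#' correlation between predictions and targets. Dimensions with constant
#' predictions yield `NA` (undefined correlation) rather than an error.
#'
#' @param model A decoder with a `predict` method (`bci_ridge`, `bci_ffn`,
#'   `bci_rnn`) or a function `features -> predictions`.
#' @param features bins x channels matrix (preprocessed like the training
#'   data).
#' @param targets bins x 4 velocity targets.
#' @return List with `predictions` and `r` (length-4 named vector).
#' @export
decode_offline <- function(model, features, targets) {
  pred <- if (is.function(model)) model(as.matrix(features))
          else stats::predict(model, as.matrix(features))
  targets <- as.matrix(targets)
  stopifnot(all(dim(pred) == dim(targets)))
  r <- vapply(seq_len(ncol(targets)), function(j)
    safe_cor(pred[, j], targets[, j]), numeric(1))
  names(r) <- colnames(targets) %||% paste0("dim", seq_len(ncol(targets)))
  list(predictions = pred, r = r)
}
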