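# Cross-validated population tuning statistics: per-fold OLS encoding fits,
# unbiased coefficient-vector magnitudes/correlations, context suppression
# ratios, and fitting/removal of the laterality dimension.

#' Cross-validated OLS encoding fit
#'
#' Fits the linear tuning model \eqn{f = E [1, d_{rx}, d_{ry}, d_{lx},
#' d_{ly}]'} (optionally with a trailing laterality predictor \eqn{c_{lat}})
#' by ordinary least squares on the movement-window bins of each of `k`
#' disjoint trial folds. Unimanual fits drop the inactive hand's columns.
#' Fold assignment is trial-level (bins within a trial are dependent),
#' stratified by context and direction wedge.
#'
#' @param session A `bci_session` (preprocess with [remove_block_means()]
#'   first, as the analyses assume).
#' @param context_filter Contexts (trial types) to include; `NULL` for all.
#' @param k Number of folds (>= 2).
#' @param with_laterality Include the signed laterality code as a predictor.
#' @param window Analysis window in seconds after the go cue.
#' @param seed RNG seed for fold assignment.
#' @return A `cv_fit`: list of per-fold coefficient matrices
#'   (channels x predictors), the predictor names, and the fit metadata.
#' @export
fit_encoding_cv <- function(session, context_filter = NULL, k = 5,
                            with_laterality = FALSE, window = c(0.3, 0.7),
                            seed = 1L) {
  stopifnot(inherits(session, "bci_session"), k >= 2)
  bins <- window_bins(session, context_filter, window)
  if (length(bins) == 0) stop("no movement-window bins match the context filter")
  lb <- session$labels[bins, ]
  trials <- unique(lb$trial)
  tt <- session$trial_table[match(trials, session$trial_table$trial), ]
  if (length(trials) < k) stop("fewer trials than folds in the context filter")

  predictors <- c("intercept", "rx", "ry", "lx", "ly")
  active_r <- any(lb$d_rx != 0 | lb$d_ry != 0)
  active_l <- any(lb$d_lx != 0 | lb$d_ly != 0)
  if (!active_r) predictors <- setdiff(predictors, c("rx", "ry"))
  if (!active_l) predictors <- setdiff(predictors, c("lx", "ly"))
  if (with_laterality) predictors <- c(predictors, "lat")

  X <- cbind(intercept = 1, rx = lb$d_rx, ry = lb$d_ry,
             lx = lb$d_lx, ly = lb$d_ly,
             lat = laterality_code(lb$context))[, predictors, drop = FALSE]

  # stratify by type and the active hand's wedge (right for bimanual); a
  # joint wedge_r x wedge_l stratification would leave mostly singleton strata
  strat <- paste(tt$type, ifelse(is.na(tt$wedge_r), tt$wedge_l, tt$wedge_r))
  trial_fold <- stratified_folds(length(trials), k, strat, seed)
  fold <- trial_fold[match(lb$trial, trials)]

  fold_coeffs <- vector("list", k)
  for (f in seq_len(k)) {
    rows <- fold == f
    Xf <- X[rows, , drop = FALSE]
    qx <- qr(Xf)
    if (qx$rank < ncol(Xf)) stop("rank-deficient predictors in fold ", f)
    if (kappa(crossprod(Xf)) > 1e8) {
      warning("ill-conditioned predictor matrix (condition number > 1e8)")
    }
    B <- qr.coef(qx, session$rates[bins[rows], , drop = FALSE])
    fold_coeffs[[f]] <- t(B)  # channels x predictors
    colnames(fold_coeffs[[f]]) <- predictors
  }
  structure(list(fold_coeffs = fold_coeffs, predictors = predictors,
                 window = window, k = k, n_channels = ncol(session$rates),
                 contexts = unique(lb$context)),
            class = "cv_fit")
}

#' @export
print.cv_fit <- function(x, ...) {
  cat(sprintf("<cv_fit> %d folds | %d channels | predictors: %s\n",
              x$k, x$n_channels, paste(x$predictors, collapse = ", ")))
  invisible(x)
}

fold_column <- function(fit, column) {
  if (!column %in% fit$predictors) {
    stop("predictor `", column, "` not in fit (has: ",
         paste(fit$predictors, collapse = ", "), ")")
  }
  lapply(fit$fold_coeffs, function(m) m[, column])
}

# Unbiased cross-validated squared norm: average inner product between the
# vector estimated on disjoint folds. Because estimation noise is independent
# across folds, E[<v_i, v_j>] = |v_true|^2 for i != j; the naive squared norm
# of the fold average is biased upward by the noise variance.
cv_sq_norm <- function(vs, center = FALSE) {
  if (center) vs <- lapply(vs, function(v) v - mean(v))
  k <- length(vs)
  tot <- 0; np <- 0
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    tot <- tot + sum(vs[[i]] * vs[[j]]); np <- np + 1
  }
  tot / np
}

cv_dot <- function(va, vb, center = FALSE) {
  if (center) {
    va <- lapply(va, function(v) v - mean(v))
    vb <- lapply(vb, function(v) v - mean(v))
  }
  k <- length(va)
  tot <- 0; np <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    tot <- tot + sum(va[[i]] * vb[[j]]); np <- np + 1
  }
  tot / np
}

#' Cross-validated coefficient-vector magnitude and correlation
#'
#' The squared magnitude of a coefficient column is estimated as the average
#' inner product between the column estimated on disjoint folds, which is
#' unbiased under additive zero-mean estimation noise (a naive norm of the
#' averaged coefficients is biased upward by the noise variance). The
#' cross-validated Pearson correlation between two fits' columns uses
#' cross-fold inner products of channel-centered columns, normalized by the
#' cross-validated centered norms. At high noise the estimators can
#' legitimately return squared norms below zero or correlations outside
#' \[-1, 1\]; raw values are passed through, not clipped.
#'
#' @param fit_a A `cv_fit`.
#' @param fit_b Optional second `cv_fit` (for the correlation); both fits must
#'   share the channel count. `NULL` returns the magnitude only.
#' @param column Predictor column name (e.g. `"rx"`), or a pair
#'   `c(column_a, column_b)` when correlating different columns.
#' @return List with `sq_norm` (unbiased squared magnitude), `magnitude`
#'   (`sqrt` of the squared magnitude floored at 0), and `correlation`
#'   (`NA` when `fit_b` is `NULL`).
#' @export
cv_vector_stats <- function(fit_a, fit_b = NULL, column) {
  stopifnot(inherits(fit_a, "cv_fit"))
  col_a <- column[1]
  col_b <- if (length(column) > 1) column[2] else column[1]
  va <- fold_column(fit_a, col_a)
  sq <- cv_sq_norm(va)
  corr <- NA_real_
  if (!is.null(fit_b)) {
    stopifnot(inherits(fit_b, "cv_fit"))
    if (fit_b$n_channels != fit_a$n_channels) stop("channel counts differ between fits")
    vb <- fold_column(fit_b, col_b)
    num <- cv_dot(va, vb, center = TRUE)
    den <- sqrt(cv_sq_norm(va, center = TRUE) * cv_sq_norm(vb, center = TRUE))
    corr <- num / den
  }
  list(sq_norm = sq, magnitude = sqrt(max(sq, 0)), correlation = corr)
}

#' Bimanual-to-unimanual tuning suppression ratio
#'
#' Tuning strength for a hand is the mean of the cross-validated magnitudes of
#' its x- and y-direction coefficient vectors; the suppression ratio is the
#' bimanual strength over the unimanual strength.
#'
#' @param bimanual,unimanual `cv_fit` objects for the two contexts, sharing
#'   channels.
#' @param hand `"right"` or `"left"`.
#' @return Scalar ratio.
#' @export
suppression_ratio <- function(bimanual, unimanual, hand = c("right", "left")) {
  hand <- match.arg(hand)
  if (bimanual$n_channels != unimanual$n_channels) stop("channel counts differ")
  cols <- if (hand == "right") c("rx", "ry") else c("lx", "ly")
  strength <- function(fit) mean(vapply(cols, function(cl)
    cv_vector_stats(fit, column = cl)$magnitude, numeric(1)))
  s_uni <- strength(unimanual)
  if (s_uni < 1e-10) stop("zero unimanual tuning strength for the ", hand, " hand")
  strength(bimanual) / s_uni
}

#' Fit and remove the laterality dimension
#'
#' Fits the tuning model with the signed laterality predictor on the
#' unimanual movement-window bins, takes the fitted laterality coefficient
#' column (pooled across folds), and subtracts the projection of every bin's
#' population vector onto that dimension from the whole session. Refitting
#' the model on the output yields laterality coefficients at the noise floor.
#'
#' @param session A unimanual `bci_session`.
#' @param k Folds for the laterality fit.
#' @param window Movement window for the fit.
#' @param seed RNG seed.
#' @return The session with the laterality component removed; attribute
#'   `laterality_axis` holds the unit vector that was projected out.
#' @export
remove_laterality <- function(session, k = 5, window = c(0.3, 0.7), seed = 1L) {
  fit <- fit_encoding_cv(session,
                         context_filter = c("unimanual_right", "unimanual_left"),
                         k = k, with_laterality = TRUE, window = window,
                         seed = seed)
  b_lat <- Reduce(`+`, fold_column(fit, "lat")) / fit$k
  nrm <- sqrt(sum(b_lat^2))
  if (nrm < 1e-12) return(session)  # nothing to remove
  u <- b_lat / nrm
  session$rates <- session$rates - (session$rates %*% u) %*% t(u)
  attr(session, "laterality_axis") <- u
  session
}
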