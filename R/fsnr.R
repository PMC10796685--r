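# Functional signal-to-noise ratio of decoded output, and calibration of the
# simulation's noise standard deviation against an fSNR target.

#' Functional SNR of a decoded velocity sequence
#'
#' Fits the linear model \eqn{\hat y_t = D y_t + \epsilon_t} by least squares,
#' where \eqn{y_t} is the 2-D point-at-target unit vector (normalized target
#' position minus cursor position) and \eqn{\hat y_t} the decoded velocity.
#' Returns \eqn{(D_{11} + D_{22})/2} divided by the residual standard
#' deviation averaged across both dimensions: the size of the point-at-target
#' component of the decoder output relative to trial-to-trial variability.
#'
#' @param decoded n x 2 matrix of decoded velocities.
#' @param pointing n x 2 matrix of point-at-target unit vectors.
#' @return Scalar fSNR; `Inf` if the residual is exactly zero.
#' @export
estimate_fsnr <- function(decoded, pointing) {
  decoded <- as.matrix(decoded); pointing <- as.matrix(pointing)
  stopifnot(ncol(decoded) == 2, ncol(pointing) == 2,
            nrow(decoded) == nrow(pointing))
  if (nrow(decoded) < 4) stop("need at least 4 time steps")
  if (qr(pointing)$rank < 2) stop("degenerate pointing sequence (rank < 2)")
  D <- qr.solve(pointing, decoded)        # 2x2, no intercept
  resid <- decoded - pointing %*% D
  sig <- mean(apply(resid, 2, stats::sd))
  num <- (D[1, 1] + D[2, 2]) / 2
  if (sig < 1e-12) return(Inf)
  num / sig
}

# Per-hand fSNR of a cross-validated linear decode of a (noisy, preprocessed)
# unimanual session. For each hand, held-out predictions of that hand's
# point-at-target vector are compared to the truth on that hand's trials.
session_fsnr <- function(session, k = 5, alpha = 1, seed = 1L) {
  lb <- session$labels
  X <- session$rates
  Y <- as.matrix(lb[, c("d_rx", "d_ry", "d_lx", "d_ly")])
  folds <- stratified_folds(nrow(X), k, groups = lb$context, seed = seed)
  pred <- matrix(NA_real_, nrow(X), 4)
  for (f in seq_len(k)) {
    te <- folds == f
    fit <- ridge_path(X[!te, , drop = FALSE], Y[!te, , drop = FALSE], alpha)[[1]]
    pred[te, ] <- predict_linear(fit, X[te, , drop = FALSE])
  }
  out <- c(right = NA_real_, left = NA_real_)
  rrows <- lb$context == "unimanual_right"
  lrows <- lb$context == "unimanual_left"
  if (any(rrows)) out["right"] <- estimate_fsnr(pred[rrows, 1:2], Y[rrows, 1:2])
  if (any(lrows)) out["left"] <- estimate_fsnr(pred[lrows, 3:4], Y[lrows, 3:4])
  out
}

#' Calibrate the noise standard deviation to a target fSNR
#'
#' Bisects on sigma until the per-hand fSNR of a cross-validated linear decode
#' of the noisy dataset matches `target_fsnr` (compared on the mean across
#' hands). fSNR decreases monotonically in sigma, so bisection converges.
#'
#' @param pop The generating `sim_population` (used only for error messages).
#' @param dataset A noiseless unimanual `bci_session` from
#'   [generate_unimanual_dataset()].
#' @param target_fsnr Target fSNR, a scalar or per-hand vector; > 0.
#' @param tol Absolute tolerance on the achieved mean fSNR.
#' @param sigma_range Search bracket for sigma (Hz).
#' @param max_iter Maximum bisection steps.
#' @param seed RNG seed (noise draws and fold assignment).
#' @return A [noise_model()] with the calibrated sigma; attributes
#'   `fsnr` (per-hand achieved values) and `iterations`.
#' @export
calibrate_sigma <- function(pop, dataset, target_fsnr = 2, tol = 0.1,
                            sigma_range = c(1e-3, 400), max_iter = 30,
                            seed = 1L) {
  if (any(target_fsnr <= 0)) stop("`target_fsnr` must be > 0")
  target <- mean(target_fsnr)
  measure <- function(sigma) {
    noisy <- dataset
    noisy$rates <- add_noise_and_clip(dataset$rates, noise_model(sigma), seed = seed)
    noisy <- zscore_session(remove_block_means(noisy))
    session_fsnr(noisy, seed = seed)
  }
  lo <- sigma_range[1]; hi <- sigma_range[2]
  f_lo <- mean(measure(lo)); f_hi <- mean(measure(hi))
  if (f_lo < target - tol || f_hi > target + tol) {
    stop(sprintf(paste0("target fSNR %.3g unreachable for this population: ",
                        "achieved bracket [%.3g (sigma=%.3g), %.3g (sigma=%.3g)]"),
                 target, f_hi, hi, f_lo, lo))
  }
  it <- 0L; fs <- NULL
  repeat {
    it <- it + 1L
    mid <- sqrt(lo * hi)  # sigma spans decades; bisect in log space
    fs <- measure(mid)
    fm <- mean(fs)
    if (abs(fm - target) <= tol || it >= max_iter) break
    if (fm > target) lo <- mid else hi <- mid
  }
  nm <- noise_model(mid)
  attr(nm, "fsnr") <- fs
  attr(nm, "iterations") <- it
  nm
}
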