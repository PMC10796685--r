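# Synthetic motor-cortical populations: linear directional tuning per hand,
# a direction-independent laterality axis, and context-dependent suppression /
# decorrelation of each hand's tuning in the bimanual context.

CONTEXTS <- c("unimanual_right", "unimanual_left", "bimanual", "no_movement")
DIR_COLS <- c("rx", "ry", "lx", "ly")

#' Sample a synthetic tuned population
#'
#' Draws per-channel encoding coefficients for a population of multiunit
#' channels. Each channel carries a baseline rate \eqn{b_0}, directional tuning
#' coefficients for the x/y velocity of each hand
#' (\eqn{b_{rx}, b_{ry}, b_{lx}, b_{ly}}), and a laterality coefficient
#' \eqn{b_{lat}} multiplying a signed laterality code (+1 right-hand movement,
#' -1 left-hand movement). Firing rates are linear in intended velocity within
#' a movement context:
#' \deqn{f = b_0 + b_{rx} d_{rx} + b_{ry} d_{ry} + b_{lx} d_{lx} + b_{ly} d_{ly} + b_{lat} c_{lat}}
#'
#' Left-hand directional columns are built to have a controlled correlation
#' with the matching right-hand columns: \eqn{v_l = \rho v_r +
#' \sqrt{1-\rho^2}\,w} with an independent draw \eqn{w}, then rescaled to the
#' requested norm. With `corr_mode = "exact"` (default) `w` is orthogonalized
#' against \eqn{v_r} so the realized sample correlation equals `rho` exactly;
#' `"mix"` leaves the sampling variability (~\eqn{(1-\rho^2)/\sqrt{n}}) in.
#'
#' Bimanual-context coefficients equal the unimanual ones scaled per hand by
#' `suppression`, optionally re-mixed with an independent draw so that the
#' unimanual-to-bimanual column correlation hits `bi_corr` per hand
#' (tuning-axis change, "decorrelation").
#'
#' @param n_channels Number of channels (>= 2).
#' @param rho_x,rho_y Enforced correlation between right- and left-hand x
#'   (resp. y) tuning columns, in \[-1, 1\].
#' @param lat_scale Laterality magnitude multiplier (>= 0). 1 sets the
#'   laterality column norm to the mean of the four directional column norms;
#'   0 removes the laterality dimension.
#' @param magnitudes Length-4 positive norms for the rx, ry, lx, ly columns
#'   (Hz per unit velocity). Default: right-hand norms `sqrt(n_channels)`,
#'   left-hand 0.6 of that (ipsilateral tuning is weaker).
#' @param suppression Named per-hand scaling of tuning magnitude in the
#'   bimanual context, `c(right = 1, left = 0.66)` by default.
#' @param bi_corr Named per-hand unimanual-to-bimanual tuning correlation,
#'   `c(right = 0.85, left = 0.45)` by default. Use `c(1, 1)` for pure
#'   scalar suppression without axis change.
#' @param corr_mode `"exact"` or `"mix"` (see Details).
#' @param seed RNG seed.
#' @return A `sim_population` object.
#' @export
sample_population <- function(n_channels = 192, rho_x = 0.5, rho_y = 0.5,
                              lat_scale = 1,
                              magnitudes = NULL,
                              suppression = c(right = 1, left = 0.66),
                              bi_corr = c(right = 0.85, left = 0.45),
                              corr_mode = c("exact", "mix"),
                              seed = 1L) {
  corr_mode <- match.arg(corr_mode)
  if (!is.numeric(n_channels) || n_channels < 2) stop("`n_channels` must be >= 2")
  stopifnot_scalar(rho_x, "rho_x", -1, 1)
  stopifnot_scalar(rho_y, "rho_y", -1, 1)
  stopifnot_scalar(lat_scale, "lat_scale", 0)
  if (is.null(magnitudes)) {
    magnitudes <- sqrt(n_channels) * c(rx = 1, ry = 1, lx = 0.6, ly = 0.6)
  }
  if (length(magnitudes) != 4 || any(!is.finite(magnitudes)) || any(magnitudes <= 0)) {
    stop("`magnitudes` must be 4 positive finite norms (rx, ry, lx, ly)")
  }
  magnitudes <- stats::setNames(as.numeric(magnitudes), DIR_COLS)
  suppression <- check_per_hand(suppression, "suppression", lo = 0)
  bi_corr <- check_per_hand(bi_corr, "bi_corr", lo = -1, hi = 1)

  with_seed(child_seed(seed, "population"), {
    n <- as.integer(n_channels)
    baseline <- stats::rgamma(n, shape = 4, rate = 0.1)  # ~40 Hz multiunit rates

    v_rx <- stats::rnorm(n)
    v_ry <- stats::rnorm(n)
    v_lx <- correlate_to(v_rx, stats::rnorm(n), rho_x, corr_mode)
    v_ly <- correlate_to(v_ry, stats::rnorm(n), rho_y, corr_mode)
    tuning_uni <- cbind(rx = v_rx, ry = v_ry, lx = v_lx, ly = v_ly)
    tuning_uni <- sweep(tuning_uni, 2,
                        magnitudes / sqrt(colSums(tuning_uni^2)), `*`)

    # Bimanual context: axis change (re-mix toward bi_corr) then magnitude
    # suppression, per hand.
    tuning_bi <- tuning_uni
    for (hand in c("right", "left")) {
      cols <- if (hand == "right") c("rx", "ry") else c("lx", "ly")
      for (cl in cols) {
        v <- tuning_uni[, cl]
        mixed <- correlate_to(v, stats::rnorm(n), bi_corr[[hand]], corr_mode)
        mixed <- mixed * (sqrt(sum(v^2)) / sqrt(sum(mixed^2)))
        tuning_bi[, cl] <- mixed * suppression[[hand]]
      }
    }

    lat_ref_norm <- mean(magnitudes)
    laterality <- stats::rnorm(n)
    laterality <- if (lat_scale == 0) {
      rep(0, n)
    } else {
      laterality * (lat_scale * lat_ref_norm / sqrt(sum(laterality^2)))
    }

    structure(list(
      n_channels = n, baseline = baseline,
      tuning_uni = tuning_uni, tuning_bi = tuning_bi,
      laterality = laterality,
      rho_x = rho_x, rho_y = rho_y, lat_scale = lat_scale,
      magnitudes = magnitudes, suppression = suppression, bi_corr = bi_corr,
      lat_ref_norm = lat_ref_norm, corr_mode = corr_mode, seed = seed
    ), class = "sim_population")
  })
}

check_per_hand <- function(x, name, lo = -Inf, hi = Inf) {
  if (is.null(names(x))) names(x) <- c("right", "left")
  if (length(x) != 2 || !all(c("right", "left") %in% names(x)) ||
      any(!is.finite(x)) || any(x < lo) || any(x > hi)) {
    stop(sprintf("`%s` must be finite values for both hands in [%s, %s]",
                 name, format(lo), format(hi)), call. = FALSE)
  }
  x[c("right", "left")]
}

# v_target = rho * v_ref + sqrt(1 - rho^2) * w. In "exact" mode w is first
# residualized against v_ref (and both standardized on centered values) so
# cor(result, v_ref) == rho to machine precision.
correlate_to <- function(v_ref, w, rho, mode) {
  if (mode == "exact") {
    vc <- v_ref - mean(v_ref)
    wc <- w - mean(w)
    wc <- wc - vc * sum(wc * vc) / sum(vc^2)
    vc <- vc / stats::sd(vc)
    wc <- wc / stats::sd(wc)
    rho * vc + sqrt(1 - rho^2) * wc
  } else {
    rho * v_ref + sqrt(1 - rho^2) * w
  }
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("<sim_population> %d channels | rho_x=%.2f rho_y=%.2f lat_scale=%.2f\n",
              x$n_channels, x$rho_x, x$rho_y, x$lat_scale))
  cat(sprintf("  suppression right=%.2f left=%.2f | uni-bi corr right=%.2f left=%.2f\n",
              x$suppression[["right"]], x$suppression[["left"]],
              x$bi_corr[["right"]], x$bi_corr[["left"]]))
  invisible(x)
}

#' Laterality code for a movement context
#'
#' +1 for unimanual right, -1 for unimanual left. The code is only defined by
#' the tuning model for unimanual movement; outside it we use +1 for bimanual
#' (bimanual population activity most closely resembles unimanual-right
#' activity) and 0 for no movement. Both conventions are configurable.
#'
#' @param context Character vector of contexts.
#' @param bimanual Code used in the bimanual context (default +1).
#' @param no_movement Code used at rest (default 0).
#' @return Numeric vector of codes.
#' @export
laterality_code <- function(context, bimanual = 1, no_movement = 0) {
  out <- numeric(length(context))
  out[context == "unimanual_right"] <- 1
  out[context == "unimanual_left"] <- -1
  out[context == "bimanual"] <- bimanual
  out[context == "no_movement"] <- no_movement
  out
}

#' Encode intended kinematics into noiseless firing rates
#'
#' Applies the linear tuning model channel-wise: baseline plus the
#' context-appropriate directional coefficients times intended velocity, plus
#' the laterality coefficient times the signed laterality code.
#'
#' @param pop A `sim_population`.
#' @param frames Data frame with columns `d_rx`, `d_ry`, `d_lx`, `d_ly`
#'   (intended velocity components) and `context` (one of
#'   `r toString(CONTEXTS)`).
#' @param lat_bimanual,lat_no_movement Laterality-code conventions passed to
#'   [laterality_code()].
#' @return bins x channels matrix of firing rates (Hz).
#' @export
encode_rates <- function(pop, frames, lat_bimanual = 1, lat_no_movement = 0) {
  stopifnot(inherits(pop, "sim_population"))
  need <- c("d_rx", "d_ry", "d_lx", "d_ly", "context")
  if (!all(need %in% names(frames))) {
    stop("`frames` must have columns ", toString(need))
  }
  if (!all(frames$context %in% CONTEXTS)) stop("unknown movement context in `frames`")
  d <- as.matrix(frames[, DIR_COLS_D()])
  rates <- matrix(rep(pop$baseline, each = nrow(d)), nrow(d), pop$n_channels)
  ctx <- frames$context
  for (cc in unique(ctx)) {
    rows <- which(ctx == cc)
    B <- switch(cc,
      bimanual = pop$tuning_bi,
      no_movement = NULL,
      pop$tuning_uni)
    dd <- d[rows, , drop = FALSE]
    if (cc == "unimanual_right") dd[, c("d_lx", "d_ly")] <- 0
    if (cc == "unimanual_left") dd[, c("d_rx", "d_ry")] <- 0
    if (!is.null(B)) rates[rows, ] <- rates[rows, ] + dd %*% t(B)
  }
  clat <- laterality_code(ctx, lat_bimanual, lat_no_movement)
  rates + outer(clat, pop$laterality)
}

DIR_COLS_D <- function() paste0("d_", DIR_COLS)

#' Gaussian noise model with diagonal covariance
#'
#' A single per-channel standard deviation shared across channels and bins;
#' the implied covariance across time bins is diagonal (independent bins).
#'
#' @param sigma Standard deviation (Hz), >= 0.
#' @return A `noise_model` object.
#' @export
noise_model <- function(sigma) {
  stopifnot_scalar(sigma, "sigma", 0)
  structure(list(sigma = sigma), class = "noise_model")
}

#' Add i.i.d. Gaussian noise and clip negative rates to zero
#'
#' @param rates bins x channels matrix of firing rates (Hz).
#' @param noise A [noise_model()].
#' @param seed RNG seed.
#' @return Matrix of the same shape with noise added and all entries >= 0.
#' @export
add_noise_and_clip <- function(rates, noise, seed = 1L) {
  stopifnot(inherits(noise, "noise_model"))
  with_seed(child_seed(seed, "channel-noise"), {
    noisy <- rates + matrix(stats::rnorm(length(rates), sd = noise$sigma),
                            nrow(rates), ncol(rates))
    noisy[noisy < 0] <- 0
    noisy
  })
}
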