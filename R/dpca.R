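# Demixed-PCA style marginalized variance of unimanual population activity
# over the factors: time, laterality, movement direction, and the
# laterality x direction interaction. Only the marginalized variance fractions
# are computed (no demixing axes).

# Quadrant of a direction vector; half-open angular intervals [0,90), [90,180),
# [180,270), [270,360) so on-axis directions are assigned deterministically.
direction_quadrant <- function(dx, dy) {
  ang <- atan2(dy, dx) %% (2 * pi)
  as.integer(1 + (ang %/% (pi / 2)) %% 4)
}

# Active-hand direction quadrant per trial of a unimanual session.
trial_quadrants <- function(session, trials) {
  lb <- session$labels
  vapply(trials, function(tr) {
    rows <- which(lb$trial == tr & lb$context != "no_movement")
    right <- lb$context[rows[1]] == "unimanual_right"
    if (right) direction_quadrant(lb$d_rx[rows[1]], lb$d_ry[rows[1]])
    else direction_quadrant(lb$d_lx[rows[1]], lb$d_ly[rows[1]])
  }, integer(1))
}

# Additive marginalization of a channel x lat x dir x time tensor X (already
# grand-mean centered): the time component is the lat/dir average; the
# laterality and direction components absorb their interactions with time;
# the remainder is the laterality x direction interaction.
marginalize_tensor <- function(X) {
  m_t <- apply(X, c(1, 4), mean)                   # channel x time
  m_lt <- apply(X, c(1, 2, 4), mean)               # channel x lat x time
  m_dt <- apply(X, c(1, 3, 4), mean)               # channel x dir x time
  dims <- dim(X)
  full_t <- aperm(array(m_t, c(dims[1], dims[4], dims[2], dims[3])), c(1, 3, 4, 2))
  full_l <- aperm(array(m_lt, c(dims[1], dims[2], dims[4], dims[3])), c(1, 2, 4, 3)) - full_t
  full_d <- aperm(array(m_dt, c(dims[1], dims[3], dims[4], dims[2])), c(1, 4, 2, 3)) - full_t
  full_ld <- X - full_t - full_l - full_d
  list(time = full_t, laterality = full_l, direction = full_d,
       laterality_direction = full_ld)
}

# Trial-averaged tensor for a set of trials: channels x laterality(2) x
# quadrant(4) x time bins within the movement window.
average_tensor <- function(session, trials, window) {
  lb <- session$labels
  tt <- session$trial_table
  lat_of <- ifelse(tt$type[match(trials, tt$trial)] == "unimanual_right", 1L, 2L)
  quad_of <- trial_quadrants(session, trials)
  t_bins <- sort(unique(round(
    lb$t_since_go[lb$t_since_go >= window[1] & lb$t_since_go < window[2]], 6)))
  n <- ncol(session$rates)
  X <- array(0, c(n, 2, 4, length(t_bins)))
  cnt <- array(0L, c(2, 4))
  for (i in seq_along(trials)) {
    rows <- which(lb$trial == trials[i] &
                  lb$t_since_go >= window[1] & lb$t_since_go < window[2])
    tb <- match(round(lb$t_since_go[rows], 6), t_bins)
    X[, lat_of[i], quad_of[i], tb] <-
      X[, lat_of[i], quad_of[i], tb] + t(session$rates[rows, , drop = FALSE])
    cnt[lat_of[i], quad_of[i]] <- cnt[lat_of[i], quad_of[i]] + 1L
  }
  if (any(cnt == 0)) {
    bad <- which(cnt == 0, arr.ind = TRUE)
    stop("empty laterality x direction cells: ",
         paste(sprintf("(%s, Q%d)", c("right", "left")[bad[, 1]], bad[, 2]),
               collapse = ", "))
  }
  for (l in 1:2) for (d in 1:4) X[, l, d, ] <- X[, l, d, ] / cnt[l, d]
  X
}

#' Cross-validated dPCA marginalized variance
#'
#' Builds the trial-averaged population tensor over
#' (channel x laterality x direction-quadrant x time) from unimanual trials,
#' decomposes it additively into time, laterality, direction and
#' laterality-direction marginalizations (condition factors absorb their
#' interaction with time), and estimates each factor's variance without the
#' trial-noise bias by split-half cross-validation: trials in every cell are
#' split into two halves, each half is marginalized, and the two
#' marginalizations are element-wise multiplied and summed.
#'
#' @param session A unimanual `bci_session` (block-mean removed / z-scored as
#'   desired); needs >= 2 trials per laterality x quadrant cell.
#' @param window Movement window in seconds after the go cue.
#' @param split_seed RNG seed for the split-half assignment.
#' @return A `marginal_variance` list: `cv_variance` (signed, per factor),
#'   `fraction` (negative components floored at 0, renormalized),
#'   `raw_variance` (naive within-split variances), and `total_raw_variance`.
#' @export
dpca_marginal_variance <- function(session, window = c(0.3, 0.7),
                                   split_seed = 1L) {
  stopifnot(inherits(session, "bci_session"))
  tt <- session$trial_table
  trials <- tt$trial[tt$type %in% c("unimanual_right", "unimanual_left")]
  if (length(trials) < 16) stop("need unimanual trials covering all cells")
  lat_of <- ifelse(tt$type[match(trials, tt$trial)] == "unimanual_right", 1L, 2L)
  quad_of <- trial_quadrants(session, trials)

  halves <- with_seed(child_seed(split_seed, "dpca-split"), {
    h <- integer(length(trials))
    for (l in 1:2) for (d in 1:4) {
      idx <- which(lat_of == l & quad_of == d)
      if (length(idx) < 2) {
        stop(sprintf("cell (%s, Q%d) has fewer than 2 trials",
                     c("right", "left")[l], d))
      }
      h[idx] <- sample(rep_len(1:2, length(idx)))
    }
    h
  })

  tens <- lapply(1:2, function(h) {
    X <- average_tensor(session, trials[halves == h], window)
    X - mean(X)
  })
  marg <- lapply(tens, marginalize_tensor)
  factors <- names(marg[[1]])
  cvv <- vapply(factors, function(f) sum(marg[[1]][[f]] * marg[[2]][[f]]),
                numeric(1))
  rawv <- vapply(factors, function(f)
    mean(c(sum(marg[[1]][[f]]^2), sum(marg[[2]][[f]]^2))), numeric(1))
  floored <- pmax(cvv, 0)
  frac <- if (sum(floored) > 0) floored / sum(floored) else floored
  structure(list(factors = factors, cv_variance = cvv, fraction = frac,
                 raw_variance = rawv,
                 total_raw_variance = mean(c(sum(tens[[1]]^2), sum(tens[[2]]^2)))),
            class = "marginal_variance")
}

#' @export
print.marginal_variance <- function(x, ...) {
  df <- data.frame(factor = x$factors,
                   cv_variance = signif(x$cv_variance, 4),
                   fraction = round(x$fraction, 3))
  print(df, row.names = FALSE)
  invisible(x)
}
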