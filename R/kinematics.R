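# Cursor speed profiles used for open-loop trajectories and decoder velocity
# targets.

#' Minimum-jerk and saturated speed profiles
#'
#' The open-loop cursors follow a minimum-jerk trajectory: position along the
#' straight-line path is the fifth-order polynomial
#' \eqn{x(\tau) = 10\tau^3 - 15\tau^4 + 6\tau^5}, whose speed is zero at both
#' endpoints and peaks at \eqn{1.875 \cdot distance / duration} at
#' \eqn{\tau = 0.5}.
#'
#' The saturated profile better approximates a user's intention to move at
#' maximum speed whenever far from the target: zero during the reaction time,
#' then constant at maximum speed, then a linear taper to zero that begins
#' when the remaining distance falls below `taper_frac` of the total. Both
#' profiles are renormalized on the discrete grid so that
#' `sum(speed) * bin == distance` exactly.
#'
#' @param distance Total displacement (workspace units), > 0.
#' @param move_duration Movement duration in seconds.
#' @param reaction_time Reaction time in seconds (saturated profile only),
#'   must be < `move_duration`.
#' @param bin Bin width in seconds (default 0.02).
#' @param taper_frac Fraction of the distance covered during the final taper.
#' @return List with numeric vectors `minjerk` and `saturated` (speeds per
#'   bin, units/s), each of length `round(move_duration / bin)`.
#' @export
kinematic_profiles <- function(distance, move_duration, reaction_time = 0.2,
                               bin = 0.02, taper_frac = 0.15) {
  stopifnot_scalar(distance, "distance", lo = 1e-12)
  stopifnot_scalar(move_duration, "move_duration", lo = bin)
  stopifnot_scalar(reaction_time, "reaction_time", lo = 0)
  if (reaction_time >= move_duration) stop("`reaction_time` must be < `move_duration`")
  n <- max(2L, as.integer(round(move_duration / bin)))
  # bin-center times
  tt <- (seq_len(n) - 0.5) * bin
  tau <- tt / move_duration
  minjerk <- (distance / move_duration) * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
  minjerk <- minjerk * distance / (sum(minjerk) * bin)

  active <- move_duration - reaction_time
  v_max <- (1 + taper_frac) * distance / active
  taper_time <- 2 * taper_frac * distance / v_max
  t_act <- tt - reaction_time
  saturated <- ifelse(t_act < 0, 0,
               ifelse(t_act < active - taper_time, v_max,
                      pmax(0, v_max * (active - t_act) / taper_time)))
  saturated <- saturated * distance / (sum(saturated) * bin)
  list(minjerk = minjerk, saturated = saturated)
}
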