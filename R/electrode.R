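# Electrode-level tuning: per-trial mean rates in the movement window,
# one-way ANOVA over the four direction quadrants, and the FVAF score
# (fraction of firing-rate variance accounted for by movement direction).

#' Per-electrode direction tuning (ANOVA and FVAF)
#'
#' For each electrode, per-trial average firing rates within the movement
#' window are grouped by the moving hand's direction quadrant (for bimanual
#' trials, grouping by one hand ignores the other hand's direction). A 1-way
#' ANOVA gives a tuning p-value (electrodes with p below `p_threshold` are
#' flagged strongly tuned), and tuning strength is summarized by
#' \deqn{FVAF = SS_{dir} / SS_{total}}
#' with \eqn{SS_{total} = \sum_i (f_i - \bar f)^2} and
#' \eqn{SS_{dir} = \sum_i (\bar f_{D[i]} - \bar f)^2}, where \eqn{f_i} is
#' trial i's mean rate, \eqn{\bar f} the grand mean and \eqn{\bar f_{D[i]}}
#' the mean over trials sharing trial i's cued quadrant. FVAF ranges from 0
#' (no direction-related variance) to 1.
#'
#' @param session A `bci_session`.
#' @param context `"unimanual_right"`, `"unimanual_left"`, or `"bimanual"`.
#' @param hand Hand whose direction defines the grouping; defaults to the
#'   moving hand for unimanual contexts and must be given for bimanual.
#' @param window Movement window (s after go).
#' @param p_threshold Strong-tuning p-value threshold (default 1e-5).
#' @return Data frame, one row per electrode: `p_value`, `fvaf`, `tuned`.
#'   Electrodes with zero total variance get `NA` FVAF.
#' @export
electrode_tuning <- function(session, context, hand = NULL,
                             window = c(0.3, 0.7), p_threshold = 1e-5) {
  stopifnot(inherits(session, "bci_session"))
  if (is.null(hand)) {
    hand <- switch(context, unimanual_right = "right", unimanual_left = "left",
                   stop("`hand` must be given for the bimanual context"))
  }
  tt <- session$trial_table
  trials <- tt$trial[tt$type == context]
  lb <- session$labels
  f_trial <- t(matrix(vapply(trials, function(tr) {
    rows <- which(lb$trial == tr & lb$t_since_go >= window[1] &
                  lb$t_since_go < window[2])
    colMeans(session$rates[rows, , drop = FALSE])
  }, numeric(ncol(session$rates))), nrow = ncol(session$rates)))

  quad <- vapply(trials, function(tr) {
    rows <- which(lb$trial == tr & lb$context != "no_movement")
    if (hand == "right") direction_quadrant(lb$d_rx[rows[1]], lb$d_ry[rows[1]])
    else direction_quadrant(lb$d_lx[rows[1]], lb$d_ly[rows[1]])
  }, integer(1))
  if (min(table(quad)) < 2) stop("need >= 2 trials per direction quadrant")
  grp <- factor(quad, levels = 1:4)

  res <- apply(f_trial, 2, function(f) {
    ss_total <- sum((f - mean(f))^2)
    if (ss_total < 1e-12) return(c(NA_real_, NA_real_))
    p <- stats::oneway.test(f ~ grp, var.equal = TRUE)$p.value
    group_mean <- tapply(f, grp, mean)
    ss_dir <- sum((group_mean[as.integer(grp)] - mean(f))^2)
    c(p, ss_dir / ss_total)
  })
  data.frame(electrode = seq_len(ncol(f_trial)),
             p_value = res[1, ], fvaf = res[2, ],
             tuned = !is.na(res[1, ]) & res[1, ] < p_threshold)
}

#' PCA view of laterality coding
#'
#' Performs PCA on per-trial mean firing-rate vectors from the movement
#' window (the session should be z-scored) and returns the per-trial scores
#' in the top two PCs together with each trial's time course projected onto
#' PC1 over a window around the go cue. With a salient laterality dimension,
#' unimanual left and right trials separate linearly in the top PCs.
#'
#' @param session A z-scored `bci_session`.
#' @param window Movement window (s after go) for the trial-mean vectors.
#' @param time_window Window (s relative to go) for the PC1 time course.
#' @return List: `scores` (trials x 2), `trial_type`, `explained` (variance
#'   fractions of the top PCs), `pc1_time` (trials x time matrix) and
#'   `pc1_t` (bin times).
#' @export
pca_laterality_view <- function(session, window = c(0.3, 0.7),
                                time_window = c(-0.5, 1.5)) {
  stopifnot(inherits(session, "bci_session"))
  tt <- session$trial_table
  lb <- session$labels
  trials <- tt$trial
  f_trial <- t(matrix(vapply(trials, function(tr) {
    rows <- which(lb$trial == tr & lb$t_since_go >= window[1] &
                  lb$t_since_go < window[2])
    colMeans(session$rates[rows, , drop = FALSE])
  }, numeric(ncol(session$rates))), nrow = ncol(session$rates)))
  pc <- stats::prcomp(f_trial, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1:2, drop = FALSE]

  t_grid <- sort(unique(round(lb$t_since_go[
    lb$t_since_go >= time_window[1] & lb$t_since_go < time_window[2]], 6)))
  pc1 <- matrix(NA_real_, length(trials), length(t_grid))
  ctr <- sweep(session$rates, 2, pc$center)
  proj <- drop(ctr %*% pc$rotation[, 1])
  for (i in seq_along(trials)) {
    rows <- which(lb$trial == trials[i] &
                  lb$t_since_go >= time_window[1] & lb$t_since_go < time_window[2])
    pc1[i, match(round(lb$t_since_go[rows], 6), t_grid)] <- proj[rows]
  }
  list(scores = scores, trial_type = tt$type,
       explained = (pc$sdev^2 / sum(pc$sdev^2))[1:2],
       pc1_time = pc1, pc1_t = t_grid)
}
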