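# Session containers: binned firing-rate tensors with per-bin kinematic and
# context labels plus a trial table, and the generators that produce them.

BIN_WIDTH <- 0.02  # 20-ms bins throughout

#' Construct a session object
#'
#' @param rates bins x channels matrix of firing rates.
#' @param labels Per-bin data frame: `trial`, `t_since_go` (s), `epoch`
#'   (`"delay"`, `"move"`, `"idle"`), `context`, `d_rx`..`d_ly` (intended
#'   velocity), `v_rx`..`v_ly` (decoder velocity targets).
#' @param trial_table Per-trial data frame (type, wedges, epoch bin ranges).
#' @param bin_width Bin width in seconds (must be 0.02).
#' @param preprocessing List recording preprocessing applied so far.
#' @return A `bci_session` object.
#' @export
bci_session <- function(rates, labels, trial_table, bin_width = BIN_WIDTH,
                        preprocessing = list(block_means_removed = FALSE,
                                             zscored = FALSE)) {
  stopifnot(is.matrix(rates), nrow(rates) == nrow(labels))
  if (abs(bin_width - BIN_WIDTH) > 1e-12) stop("bin width must be exactly 20 ms")
  structure(list(rates = rates, labels = labels, trial_table = trial_table,
                 bin_width = bin_width, preprocessing = preprocessing),
            class = "bci_session")
}

#' @export
print.bci_session <- function(x, ...) {
  cat(sprintf("<bci_session> %d bins x %d channels | %d trials | %s\n",
              nrow(x$rates), ncol(x$rates), nrow(x$trial_table),
              paste(names(which(unlist(x$preprocessing))), collapse = ", ")))
  invisible(x)
}

# Uniformly random unit vector inside one of 8 half-open 45-degree wedges.
# Wedge w covers [(w-1)*45, w*45) degrees.
wedge_direction <- function(wedge) {
  ang <- ((wedge - 1) + stats::runif(length(wedge))) * (pi / 4)
  cbind(cos(ang), sin(ang))
}

# Balanced wedge assignment: counts per wedge differ by at most 1.
balanced_wedges <- function(n) {
  sample(rep_len(1:8, n))
}

#' Generate a short-trial unimanual session
#'
#' Emulates movement-window data for single-bin decoding analyses: `n_per_hand`
#' trials per hand, each a fixed-length window (default 400 ms, i.e. the
#' 300-700 ms post-go movement window) in which the intended velocity is a
#' uniformly random unit vector inside the trial's direction wedge. Wedge
#' assignment is balanced across the 8 wedges per hand. Rates are noiseless
#' outputs of the tuning model; add noise with [add_noise_and_clip()].
#'
#' @param pop A [sample_population()] object.
#' @param n_per_hand Trials per hand (>= 8 to balance the 8 wedges).
#' @param trial_len Trial length in seconds (default 0.4).
#' @param seed RNG seed.
#' @return A `bci_session`; every bin has `epoch == "move"`.
#' @export
generate_unimanual_dataset <- function(pop, n_per_hand = 2000, trial_len = 0.4,
                                       seed = 1L) {
  stopifnot(inherits(pop, "sim_population"))
  if (n_per_hand < 8) stop("`n_per_hand` must be >= 8 (cannot balance the 8 wedges)")
  bins_per_trial <- as.integer(round(trial_len / BIN_WIDTH))
  with_seed(child_seed(seed, "unimanual-dataset"), {
    n_trials <- 2L * n_per_hand
    type <- sample(rep(c("unimanual_right", "unimanual_left"), n_per_hand))
    wedge <- integer(n_trials)
    wedge[type == "unimanual_right"] <- balanced_wedges(n_per_hand)
    wedge[type == "unimanual_left"] <- balanced_wedges(n_per_hand)
    dirs <- wedge_direction(wedge)

    right <- type == "unimanual_right"
    trial_table <- data.frame(
      trial = seq_len(n_trials), type = type,
      wedge_r = ifelse(right, wedge, NA),
      wedge_l = ifelse(right, NA, wedge),
      n_bins = bins_per_trial,
      start_bin = (seq_len(n_trials) - 1L) * bins_per_trial + 1L)

    idx <- rep(seq_len(n_trials), each = bins_per_trial)
    labels <- data.frame(
      trial = idx,
      t_since_go = 0.3 + (rep(seq_len(bins_per_trial), n_trials) - 0.5) * BIN_WIDTH,
      epoch = "move",
      context = type[idx],
      d_rx = ifelse(right[idx], dirs[idx, 1], 0),
      d_ry = ifelse(right[idx], dirs[idx, 2], 0),
      d_lx = ifelse(right[idx], 0, dirs[idx, 1]),
      d_ly = ifelse(right[idx], 0, dirs[idx, 2]))
    labels$v_rx <- labels$d_rx; labels$v_ry <- labels$d_ry
    labels$v_lx <- labels$d_lx; labels$v_ly <- labels$d_ly

    rates <- encode_rates(pop, labels)
    bci_session(rates, labels, trial_table)
  })
}

#' Generate a delayed-movement session
#'
#' Emulates the open-loop calibration task: each trial has a preparatory
#' *delay* (1-2 s, uniform), a *move* period (1-2 s) during which the cursors
#' travel to their targets, and an *idle* rest period. Trial types
#' (unimanual right / unimanual left / bimanual) are interleaved and balanced,
#' as are direction wedges within each hand. During the move period the
#' intended (encoded) velocity is the unit point-at-target direction, active
#' from `reaction_time` after the go cue; the stored decoder velocity targets
#' `v_*` follow the saturated speed profile of [kinematic_profiles()].
#'
#' @param pop A `sim_population`.
#' @param n_per_type Trials per movement type.
#' @param types Movement types to include.
#' @param idle_duration Rest period length in seconds.
#' @param reaction_time Prescribed reaction time in seconds; the stored
#'   velocity targets assume it.
#' @param reaction_jitter Range (s) of additional per-trial delay of the
#'   *actual* intention onset beyond `reaction_time`. The participant's real
#'   reaction varies trial to trial while the regressed targets prescribe a
#'   fixed one, so the encoded rates and the stored targets are deliberately
#'   misaligned by this much — the label mismatch a recurrent decoder can
#'   exploit by learning the task clock. `c(0, 0)` for perfectly aligned
#'   labels.
#' @param target_distance Reach distance in workspace units.
#' @param seed RNG seed.
#' @return A `bci_session` with delay/move/idle epoch annotations.
#' @export
generate_delayed_session <- function(pop, n_per_type = 40,
                                     types = c("unimanual_right",
                                               "unimanual_left", "bimanual"),
                                     idle_duration = 1,
                                     reaction_time = 0.2,
                                     reaction_jitter = c(0, 0),
                                     target_distance = 0.7,
                                     seed = 1L) {
  stopifnot(inherits(pop, "sim_population"))
  if (n_per_type < 8) stop("`n_per_type` must be >= 8 (cannot balance the 8 wedges)")
  with_seed(child_seed(seed, "delayed-session"), {
    n_types <- length(types)
    n_trials <- n_per_type * n_types
    type <- sample(rep(types, n_per_type))
    wedge_r <- rep(NA_integer_, n_trials)
    wedge_l <- rep(NA_integer_, n_trials)
    r_active <- type %in% c("unimanual_right", "bimanual")
    l_active <- type %in% c("unimanual_left", "bimanual")
    wedge_r[r_active] <- balanced_wedges(sum(r_active))
    wedge_l[l_active] <- balanced_wedges(sum(l_active))
    delay_dur <- stats::runif(n_trials, 1, 2)
    move_dur <- stats::runif(n_trials, 1, 2)

    per_trial <- vector("list", n_trials)
    rows <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      nd <- as.integer(round(delay_dur[i] / BIN_WIDTH))
      nm <- as.integer(round(move_dur[i] / BIN_WIDTH))
      ni <- as.integer(round(idle_duration / BIN_WIDTH))
      nb <- nd + nm + ni
      epoch <- rep(c("delay", "move", "idle"), c(nd, nm, ni))
      t_go <- (seq_len(nb) - nd - 0.5) * BIN_WIDTH

      dir_r <- if (r_active[i]) wedge_direction(wedge_r[i]) else matrix(0, 1, 2)
      dir_l <- if (l_active[i]) wedge_direction(wedge_l[i]) else matrix(0, 1, 2)
      prof <- kinematic_profiles(target_distance, nm * BIN_WIDTH,
                                 reaction_time = reaction_time)
      speed <- prof$saturated
      moving <- speed > 0
      # targets follow the prescribed profile; the *encoded* intention starts
      # at the trial's actual (jittered) reaction and runs to movement end
      onset <- reaction_time + stats::runif(1, reaction_jitter[1],
                                            reaction_jitter[2])
      t_move <- (seq_len(nm) - 0.5) * BIN_WIDTH
      intending <- t_move >= onset & t_move <= max(t_move[moving])
      d_r <- matrix(0, nb, 2); d_l <- matrix(0, nb, 2)
      v_r <- matrix(0, nb, 2); v_l <- matrix(0, nb, 2)
      mrows <- which(epoch == "move")
      vnorm <- speed / max(speed)
      if (r_active[i]) {
        d_r[mrows[intending], ] <- rep(dir_r, each = sum(intending))
        v_r[mrows, ] <- outer(vnorm, dir_r[1, ])
      }
      if (l_active[i]) {
        d_l[mrows[intending], ] <- rep(dir_l, each = sum(intending))
        v_l[mrows, ] <- outer(vnorm, dir_l[1, ])
      }
      # `context` reflects what the participant is actually doing (drives the
      # encoding); `cued_context` is the task-prescribed label a decoder
      # would be trained against
      context <- rep("no_movement", nb)
      context[mrows[intending]] <- type[i]
      cued <- rep("no_movement", nb)
      cued[mrows[moving]] <- type[i]

      rows[[i]] <- data.frame(
        trial = i, t_since_go = t_go, epoch = epoch, context = context,
        cued_context = cued,
        d_rx = d_r[, 1], d_ry = d_r[, 2], d_lx = d_l[, 1], d_ly = d_l[, 2],
        v_rx = v_r[, 1], v_ry = v_r[, 2], v_lx = v_l[, 1], v_ly = v_l[, 2])
      per_trial[[i]] <- data.frame(
        trial = i, type = type[i], wedge_r = wedge_r[i], wedge_l = wedge_l[i],
        delay_bins = nd, move_bins = nm, idle_bins = ni, n_bins = nb)
    }
    labels <- do.call(rbind, rows)
    trial_table <- do.call(rbind, per_trial)
    trial_table$start_bin <- cumsum(c(1L, utils::head(trial_table$n_bins, -1L)))
    rates <- encode_rates(pop, labels)
    bci_session(rates, labels, trial_table)
  })
}

#' Remove block-wise channel means
#'
#' Subtracts per-channel means computed within contiguous trial blocks,
#' adjusting for slow nonstationarities. Synthetic sessions default to a
#' single block.
#'
#' @param session A `bci_session`.
#' @param n_blocks Number of contiguous trial blocks.
#' @return The session with means removed and the preprocessing record updated.
#' @export
remove_block_means <- function(session, n_blocks = 1) {
  stopifnot(inherits(session, "bci_session"))
  trials <- session$trial_table$trial
  block_of_trial <- if (n_blocks == 1) rep(1L, length(trials)) else
    as.integer(cut(seq_along(trials), breaks = n_blocks, labels = FALSE))
  block <- block_of_trial[match(session$labels$trial, trials)]
  for (b in unique(block)) {
    rows <- which(block == b)
    session$rates[rows, ] <- sweep(session$rates[rows, , drop = FALSE], 2,
                                   colMeans(session$rates[rows, , drop = FALSE]))
  }
  session$preprocessing$block_means_removed <- TRUE
  session
}

#' Z-score channels
#'
#' Per-channel standardization; the means/SDs used are stored so that online
#' decoding can apply the same transform to incoming bins.
#'
#' @param session A `bci_session`.
#' @param stats Optional list with `mean` and `sd` vectors to reuse (e.g. the
#'   training session's statistics).
#' @return The session, z-scored, with `preprocessing$zscore_stats` set.
#' @export
zscore_session <- function(session, stats = NULL) {
  stopifnot(inherits(session, "bci_session"))
  if (is.null(stats)) {
    mu <- colMeans(session$rates)
    sd <- apply(session$rates, 2, stats::sd)
    sd[sd < 1e-8] <- 1
    stats <- list(mean = mu, sd = sd)
  }
  session$rates <- sweep(sweep(session$rates, 2, stats$mean), 2, stats$sd, `/`)
  session$preprocessing$zscored <- TRUE
  session$preprocessing$zscore_stats <- stats
  session
}

# Bins inside the movement analysis window (t_since_go in [window[1], window[2]))
# belonging to the given contexts.
window_bins <- function(session, contexts = NULL, window = c(0.3, 0.7)) {
  lb <- session$labels
  keep <- lb$epoch == "move" &
    lb$t_since_go >= window[1] & lb$t_since_go < window[2]
  if (!is.null(contexts)) {
    keep <- keep & session$trial_table$type[lb$trial] %in% contexts
  }
  which(keep)
}
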