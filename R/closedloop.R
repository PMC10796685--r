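# Simulated two-cursor closed-loop task: dwell/timeout mechanics, error and
# push assistance, lock mode, a simulated user that emits synthetic neural
# activity from point-at-target intentions, and online performance metrics
# (time-to-acquisition, angular error, cursor jitter).

#' Closed-loop task configuration
#'
#' @param target_radius Target radius (workspace units, workspace is
#'   \[-1, 1\]^2).
#' @param target_distance Distance from a cursor's start to its target.
#' @param dwell Required uninterrupted simultaneous dwell (s).
#' @param timeout Trial timeout (s).
#' @param gain Output gain: decoded velocities are scaled by `gain`
#'   (workspace units/s per unit decoded velocity) before integration.
#' @param dt Control-loop step (s); one 20-ms bin.
#' @return Named list.
#' @export
task_config <- function(target_radius = 0.15, target_distance = 0.7,
                        dwell = 0.5, timeout = 10, gain = 0.5, dt = 0.02) {
  as.list(environment())
}

#' Assistance configuration
#'
#' Error assistance attenuates the component of each cursor's velocity
#' orthogonal to its straight-line path to the target by `1 - error_assist`.
#' Push assistance adds a unit vector toward the target scaled by
#' `push_assist` times the decoded cursor speed. Lock mode fixes the
#' non-active cursor during unimanual trials.
#'
#' @param error_assist,push_assist Scalars in \[0, 1\].
#' @param lock_mode Fix the non-active cursor.
#' @return An `assist_config` list.
#' @export
assist_config <- function(error_assist = 0, push_assist = 0, lock_mode = FALSE) {
  stopifnot_scalar(error_assist, "error_assist", 0, 1)
  stopifnot_scalar(push_assist, "push_assist", 0, 1)
  structure(as.list(environment()), class = "assist_config")
}

# Fresh trial state. Cursors start at the workspace center; each active
# cursor's target sits `target_distance` away in a random direction, the
# non-active cursor's target is its start position (it must stay put).
new_trial_state <- function(type, config, seed) {
  with_seed(seed, {
    ang <- stats::runif(2, 0, 2 * pi)
    pos <- list(right = c(0, 0), left = c(0, 0))
    target <- pos
    if (type %in% c("unimanual_right", "bimanual")) {
      target$right <- config$target_distance * c(cos(ang[1]), sin(ang[1]))
    }
    if (type %in% c("unimanual_left", "bimanual")) {
      target$left <- config$target_distance * c(cos(ang[2]), sin(ang[2]))
    }
    structure(list(type = type, pos = pos, target = target,
                   dwell = c(right = 0, left = 0), t = 0,
                   done = FALSE, success = FALSE, tta = NA_real_),
              class = "task_state")
  })
}

active_cursors <- function(type) {
  switch(type,
         unimanual_right = "right", unimanual_left = "left",
         bimanual = c("right", "left"), character(0))
}

#' Advance the closed-loop task by one bin
#'
#' Applies assistance to the decoded velocities, integrates cursor positions,
#' and updates the dwell timers and trial outcome. Per cursor the decoded
#' velocity is decomposed into components along and orthogonal to the
#' cursor-to-target line; the orthogonal component is multiplied by
#' `1 - error_assist`, then `push_assist * speed` of assistance is added
#' along the target direction (`speed` is the decoded cursor speed). A locked
#' non-active cursor does not move. The trial succeeds at the first bin where
#' both dwell timers reach the dwell requirement simultaneously; a cursor
#' leaving its target resets its timer. The trial fails at timeout.
#'
#' @param state A `task_state`.
#' @param velocities Length-4 decoded velocity (right x/y, left x/y), already
#'   scaled by the output gain (units/s).
#' @param assist An [assist_config()].
#' @param config A [task_config()].
#' @return The updated `task_state`.
#' @export
task_step <- function(state, velocities, assist = assist_config(),
                      config = task_config()) {
  stopifnot(inherits(state, "task_state"), all(is.finite(velocities)))
  if (state$done) return(state)
  dt <- config$dt
  act <- active_cursors(state$type)
  for (cursor in c("right", "left")) {
    v <- velocities[if (cursor == "right") 1:2 else 3:4]
    if (assist$lock_mode && !cursor %in% act) v <- c(0, 0)
    else {
      to_t <- state$target[[cursor]] - state$pos[[cursor]]
      if (sqrt(sum(to_t^2)) > 1e-9) {
        u <- unit_vec(to_t)
        speed <- sqrt(sum(v^2))
        along <- sum(v * u)
        ortho <- v - along * u
        v <- along * u + (1 - assist$error_assist) * ortho
        v <- v + assist$push_assist * speed * u
      }
    }
    p <- state$pos[[cursor]] + v * dt
    state$pos[[cursor]] <- pmax(-1, pmin(1, p))
    inside <- sqrt(sum((state$pos[[cursor]] - state$target[[cursor]])^2)) <=
      config$target_radius
    state$dwell[[cursor]] <- if (inside) state$dwell[[cursor]] + dt else 0
  }
  state$t <- state$t + dt
  if (all(state$dwell >= config$dwell - 1e-9)) {
    state$done <- TRUE; state$success <- TRUE; state$tta <- state$t
  } else if (state$t >= config$timeout - 1e-9) {
    state$done <- TRUE; state$success <- FALSE; state$tta <- config$timeout
  }
  state
}

#' Simulated user
#'
#' Emits one bin of synthetic neural activity per 20-ms step: the intention
#' for each attended cursor is the unit vector pointing from the cursor to
#' its target (zero once the cursor is inside the target, and zero within the
#' reaction time of the go cue), encoded through the population with
#' context-appropriate coefficients.
#'
#' With the `"sequential"` strategy the user attends one cursor at a time on
#' bimanual trials (the one farther from its target, with a hysteresis of
#' `switch_hysteresis` bins to avoid chatter); with `"simultaneous"` both
#' cursors are attended.
#'
#' @param pop The `sim_population` generating the user's neural activity.
#' @param strategy `"simultaneous"` or `"sequential"`.
#' @param reaction_time Seconds after the go cue with zero intention.
#' @param intention_noise SD (radians) of a slowly wandering rotation applied
#'   to the pointed direction, modeling imprecise aiming that the user then
#'   has to correct; 0 for a perfectly aimed user. The perturbation follows
#'   an AR(1) process with coefficient `intention_ar` per bin.
#' @param intention_ar Autocorrelation of the aiming error across bins.
#' @param switch_hysteresis Minimum bins between attention switches
#'   (sequential strategy).
#' @return A `sim_user`.
#' @export
sim_user <- function(pop, strategy = c("simultaneous", "sequential"),
                     reaction_time = 0.2, intention_noise = 0,
                     intention_ar = 0.9, switch_hysteresis = 3) {
  strategy <- match.arg(strategy)
  structure(list(pop = pop, strategy = strategy,
                 reaction_time = reaction_time,
                 intention_noise = intention_noise,
                 intention_ar = intention_ar,
                 switch_hysteresis = switch_hysteresis),
            class = "sim_user")
}

# Which cursors the user attends this bin; `mem` carries sequential-strategy
# attention state.
attended_cursors <- function(user, state, mem) {
  act <- active_cursors(state$type)
  if (user$strategy == "simultaneous" || length(act) < 2) {
    return(list(cursors = act, mem = mem))
  }
  dist <- vapply(act, function(cc)
    sqrt(sum((state$target[[cc]] - state$pos[[cc]])^2)), numeric(1))
  inside <- dist <= 1e-9
  prefer <- act[which.max(dist)]
  if (is.null(mem$current) || mem$since >= user$switch_hysteresis) {
    if (!identical(mem$current, prefer)) {
      mem$current <- prefer; mem$since <- 0L
    }
  }
  mem$since <- (mem$since %||% 0L) + 1L
  list(cursors = mem$current, mem = mem)
}

#' One bin of simulated user activity
#'
#' @param user A [sim_user()].
#' @param state Current `task_state`.
#' @param noise A [noise_model()] (or `NULL` for noiseless).
#' @param seed Seed for this bin's noise draw.
#' @param mem Internal attention memory (sequential strategy); pass the `mem`
#'   returned by the previous call.
#' @param config A [task_config()] (for the target radius).
#' @return List: `rates` (length-N bin vector, Hz), `intention` (length 4),
#'   `context` (encoding context used), `mem`.
#' @export
user_step <- function(user, state, noise = NULL, seed = 1L, mem = list(),
                      config = task_config()) {
  att <- attended_cursors(user, state, mem)
  mem <- att$mem
  # slowly wandering aiming error per hand (AR(1) in the pointing angle)
  if (user$intention_noise > 0) {
    prev <- mem$aim %||% c(right = 0, left = 0)
    innov <- with_seed(child_seed(seed, "aim"),
                       stats::rnorm(2, sd = user$intention_noise *
                                      sqrt(1 - user$intention_ar^2)))
    mem$aim <- user$intention_ar * prev + innov
  }
  intention <- c(0, 0, 0, 0)
  if (state$t >= user$reaction_time) {
    for (cc in att$cursors) {
      to_t <- state$target[[cc]] - state$pos[[cc]]
      if (sqrt(sum(to_t^2)) > config$target_radius) {
        ix <- if (cc == "right") 1:2 else 3:4
        u <- unit_vec(to_t)
        if (user$intention_noise > 0) {
          a <- mem$aim[[cc]]
          u <- c(cos(a) * u[1] - sin(a) * u[2],
                 sin(a) * u[1] + cos(a) * u[2])
        }
        intention[ix] <- u
      }
    }
  }
  moving_r <- any(intention[1:2] != 0); moving_l <- any(intention[3:4] != 0)
  context <- if (moving_r && moving_l) "bimanual"
    else if (moving_r) "unimanual_right"
    else if (moving_l) "unimanual_left" else "no_movement"
  frame <- data.frame(d_rx = intention[1], d_ry = intention[2],
                      d_lx = intention[3], d_ly = intention[4],
                      context = context)
  rates <- encode_rates(user$pop, frame)
  if (!is.null(noise)) rates <- add_noise_and_clip(rates, noise, seed = seed)
  list(rates = drop(rates), intention = intention, context = context,
       mem = mem)
}

# ---- decoder step dispatch (one bin in, four velocities out) ----

#' Oracle and zero reference decoders
#'
#' `oracle_decoder()` outputs the true point-at-target unit vector for every
#' active cursor (an upper bound on closed-loop performance);
#' `zero_decoder()` always outputs zero velocity (a lower bound: every trial
#' times out).
#'
#' @return Decoder objects usable with [run_trials()].
#' @export
oracle_decoder <- function() structure(list(), class = "oracle_decoder")

#' @rdname oracle_decoder
#' @export
zero_decoder <- function() structure(list(), class = "zero_decoder")

decoder_step <- function(model, x, dstate, task_state) UseMethod("decoder_step")

#' @export
decoder_step.bci_rnn <- function(model, x, dstate, task_state) {
  st <- rnn_step(model, x, state = dstate)
  list(velocity = st$velocity, state = st$state)
}

#' @export
decoder_step.bci_ridge <- function(model, x, dstate, task_state) {
  list(velocity = drop(stats::predict(model, matrix(x, 1))), state = dstate)
}

#' @export
decoder_step.bci_ffn <- decoder_step.bci_ridge

#' @export
decoder_step.oracle_decoder <- function(model, x, dstate, task_state) {
  v <- c(0, 0, 0, 0)
  for (cc in active_cursors(task_state$type)) {
    ix <- if (cc == "right") 1:2 else 3:4
    v[ix] <- unit_vec(task_state$target[[cc]] - task_state$pos[[cc]])
  }
  list(velocity = v, state = dstate)
}

#' @export
decoder_step.zero_decoder <- function(model, x, dstate, task_state) {
  list(velocity = c(0, 0, 0, 0), state = dstate)
}

#' @export
decoder_step.function <- function(model, x, dstate, task_state) {
  list(velocity = model(x), state = dstate)
}

#' Run simulated closed-loop trials
#'
#' Full closed loop: each 20-ms bin, the simulated user emits one bin of
#' noisy population activity from its point-at-target intention, the bin is
#' z-scored with the training statistics, the decoder maps it to cursor
#' velocities, assistance is applied, and the task state advances. Trial
#' types cycle through `types`.
#'
#' @param model A decoder (`bci_rnn`, `bci_ridge`, `bci_ffn`,
#'   [oracle_decoder()], [zero_decoder()], or a function of the bin vector).
#' @param user A [sim_user()].
#' @param noise A [noise_model()] for the user's activity, or `NULL`.
#' @param zstats `list(mean, sd)` used to z-score decoder inputs (from the
#'   training session), or `NULL` for raw rates.
#' @param n_trials Number of trials.
#' @param types Trial types to cycle through.
#' @param config A [task_config()].
#' @param assist An [assist_config()].
#' @param angular_window Window (s after go) for the angular error.
#' @param persist_state Carry the decoder's hidden state across trials, as a
#'   continuously running online decoder would (default). `FALSE` resets the
#'   state at every go cue.
#' @param seed RNG seed.
#' @return A `closedloop_result`: `trials` data frame (type, success, tta,
#'   per-hand angular error) and `trajectories` (list of per-trial bin logs).
#' @export
run_trials <- function(model, user, noise = NULL, zstats = NULL,
                       n_trials = 24, types = c("unimanual_right",
                                                "unimanual_left"),
                       config = task_config(), assist = assist_config(),
                       angular_window = c(0.3, 0.5), persist_state = TRUE,
                       seed = 1L) {
  stopifnot(inherits(user, "sim_user"))
  if (!is.null(zstats)) {
    if (user$pop$n_channels != length(zstats$mean)) {
      stop("population and z-scoring channel counts differ")
    }
  }
  trial_rows <- vector("list", n_trials)
  trajectories <- vector("list", n_trials)
  n_steps_max <- ceiling(config$timeout / config$dt)
  dstate <- NULL
  for (tr in seq_len(n_trials)) {
    type <- types[(tr - 1L) %% length(types) + 1L]
    state <- new_trial_state(type, config, child_seed(seed, "trial", tr))
    if (!persist_state) dstate <- NULL
    mem <- list()
    log <- matrix(NA_real_, n_steps_max, 13)
    i <- 0L
    while (!state$done) {
      i <- i + 1L
      us <- user_step(user, state, noise, seed = child_seed(seed, "bin", tr, i),
                      mem = mem, config = config)
      mem <- us$mem
      x <- us$rates
      if (!is.null(zstats)) x <- (x - zstats$mean) / zstats$sd
      ds <- decoder_step(model, x, dstate, state)
      dstate <- ds$state
      v <- ds$velocity * config$gain
      log[i, ] <- c(state$t, state$pos$right, state$pos$left,
                    state$target$right, state$target$left, v)
      state <- task_step(state, v, assist, config)
    }
    log <- log[seq_len(i), , drop = FALSE]
    colnames(log) <- c("t", "prx", "pry", "plx", "ply",
                       "trx", "try", "tlx", "tly",
                       "vrx", "vry", "vlx", "vly")
    ang <- angular_errors(log, type, angular_window)
    trial_rows[[tr]] <- data.frame(trial = tr, type = type,
                                   success = state$success, tta = state$tta,
                                   ang_right = ang[["right"]],
                                   ang_left = ang[["left"]])
    trajectories[[tr]] <- log
  }
  structure(list(trials = do.call(rbind, trial_rows),
                 trajectories = trajectories, config = config,
                 assist = assist, seed = seed),
            class = "closedloop_result")
}

#' @export
print.closedloop_result <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("<closedloop_result> %d trials | success %.0f%% | mean TTA %.2f s\n",
              nrow(tr), 100 * mean(tr$success), mean(tr$tta)))
  invisible(x)
}

# Mean absolute angle (degrees) between decoded velocity (pre-assist) and the
# cursor-to-target direction over the ballistic window after the go cue.
angular_errors <- function(log, type, window = c(0.3, 0.5)) {
  out <- c(right = NA_real_, left = NA_real_)
  rows <- log[, "t"] >= window[1] & log[, "t"] < window[2]
  for (cc in active_cursors(type)) {
    if (cc == "right") { v <- log[rows, c("vrx", "vry"), drop = FALSE]
      d <- log[rows, c("trx", "try"), drop = FALSE] - log[rows, c("prx", "pry"), drop = FALSE]
    } else { v <- log[rows, c("vlx", "vly"), drop = FALSE]
      d <- log[rows, c("tlx", "tly"), drop = FALSE] - log[rows, c("plx", "ply"), drop = FALSE]
    }
    sp <- sqrt(rowSums(v^2)) * sqrt(rowSums(d^2))
    ok <- sp > 1e-9
    if (!any(ok)) next
    cosang <- pmin(1, pmax(-1, rowSums(v * d)[ok] / sp[ok]))
    out[[cc]] <- mean(abs(acos(cosang))) * 180 / pi
  }
  out
}

#' Trial metrics from a closed-loop result
#'
#' @param result A `closedloop_result`.
#' @return Data frame summarizing per trial type: success rate, mean/median
#'   TTA (s), and mean per-hand angular error (degrees).
#' @export
trial_metrics <- function(result) {
  stopifnot(inherits(result, "closedloop_result"))
  tr <- result$trials
  do.call(rbind, lapply(split(tr, tr$type), function(g) {
    data.frame(type = g$type[1], n = nrow(g), success_rate = mean(g$success),
               mean_tta = mean(g$tta), median_tta = stats::median(g$tta),
               ang_right = mean(g$ang_right, na.rm = TRUE),
               ang_left = mean(g$ang_left, na.rm = TRUE))
  }))
}

#' Cursor jitter ratio
#'
#' The ratio of a cursor's average decoded speed during its rest bins (bins
#' in which the *other* cursor should be active) to its average speed during
#' its own movement bins. Lower is better: a still non-active cursor.
#'
#' @param velocities bins x 4 decoded velocities.
#' @param active Character vector per bin: which cursor should be active
#'   (`"right"`, `"left"`, or `"none"`).
#' @return Named ratio per cursor.
#' @export
cursor_jitter <- function(velocities, active) {
  velocities <- as.matrix(velocities)
  stopifnot(nrow(velocities) == length(active))
  speed <- list(right = sqrt(rowSums(velocities[, 1:2, drop = FALSE]^2)),
                left = sqrt(rowSums(velocities[, 3:4, drop = FALSE]^2)))
  out <- c(right = NA_real_, left = NA_real_)
  for (cc in c("right", "left")) {
    other <- setdiff(c("right", "left"), cc)
    move <- active == cc; rest <- active == other
    if (!any(move)) stop("no movement bins for the ", cc, " cursor")
    out[[cc]] <- mean(speed[[cc]][rest]) / mean(speed[[cc]][move])
  }
  out
}
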