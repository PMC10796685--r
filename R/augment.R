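# Training-data alteration: label the recorded stream by movement condition,
# draw variable-length clips, dilate or compress them in time by linear
# interpolation, and append them in shuffled order into fixed-length training
# snippets under a running condition-balance record.

#' Label every bin of a session stream by movement condition
#'
#' Move bins are labeled by movement type and the moving hand's direction
#' quadrant (both hands for bimanual). No-movement bins are subdivided so
#' that preparatory and rest activity can be balanced separately: delay bins
#' take the delay subtype of the upcoming trial's type
#' (`unimanual_right_delay`, `unimanual_left_delay`, `bimanual_delay`) and
#' idle bins are labeled `rest`.
#'
#' @param session A preprocessed `bci_session` with epoch annotations.
#' @return A `labeled_stream`: `inputs` (bins x channels), `vel`
#'   (bins x 4 velocity targets), `ctx` (integer class 1..4 over
#'   `r toString(RNN_CLASSES)`), `condition` (character per bin), `trial`.
#' @export
label_stream <- function(session) {
  stopifnot(inherits(session, "bci_session"))
  lb <- session$labels
  if (anyNA(lb$epoch)) stop("session has unannotated bins")
  tt <- session$trial_table
  type <- tt$type[match(lb$trial, tt$trial)]

  # a decoder is trained against the task-prescribed (cued) labels where the
  # session distinguishes them from the participant's actual intention
  cued <- lb$cued_context %||% lb$context
  cond <- character(nrow(lb))
  move <- cued != "no_movement"
  qr_ <- direction_quadrant(lb$v_rx, lb$v_ry)
  ql_ <- direction_quadrant(lb$v_lx, lb$v_ly)
  mr <- move & cued == "unimanual_right"
  ml <- move & cued == "unimanual_left"
  mb <- move & cued == "bimanual"
  cond[mr] <- paste0("unimanual_right_Q", qr_[mr])
  cond[ml] <- paste0("unimanual_left_Q", ql_[ml])
  cond[mb] <- paste0("bimanual_Qr", qr_[mb], "Ql", ql_[mb])
  nm <- !move
  cond[nm & lb$epoch == "delay"] <- paste0(type[nm & lb$epoch == "delay"], "_delay")
  cond[nm & lb$epoch == "idle"] <- "rest"
  # move-epoch bins with zero velocity (reaction time / end of taper) count
  # as preparatory activity of their own trial type
  cond[nm & lb$epoch == "move"] <- paste0(type[nm & lb$epoch == "move"], "_delay")

  ctx <- match(cued, RNN_CLASSES)
  structure(list(inputs = session$rates,
                 vel = as.matrix(lb[, c("v_rx", "v_ry", "v_lx", "v_ly")]),
                 ctx = ctx, condition = cond, trial = lb$trial),
            class = "labeled_stream")
}

#' Split a stream into disjoint training and validation pools
#'
#' Trial-level split: no source bin appears in both pools.
#'
#' @param stream A `labeled_stream`.
#' @param validation_fraction Fraction of trials held out, in (0, 1).
#' @param seed RNG seed.
#' @return List with `train` and `validation` streams.
#' @export
split_pools <- function(stream, validation_fraction = 0.1, seed = 1L) {
  stopifnot(inherits(stream, "labeled_stream"),
            validation_fraction > 0, validation_fraction < 1)
  trials <- unique(stream$trial)
  with_seed(child_seed(seed, "pool-split"), {
    n_val <- max(1L, round(validation_fraction * length(trials)))
    val_trials <- sample(trials, n_val)
  })
  subset_stream <- function(keep) {
    structure(list(inputs = stream$inputs[keep, , drop = FALSE],
                   vel = stream$vel[keep, , drop = FALSE],
                   ctx = stream$ctx[keep], condition = stream$condition[keep],
                   trial = stream$trial[keep]),
              class = "labeled_stream")
  }
  list(train = subset_stream(!stream$trial %in% val_trials),
       validation = subset_stream(stream$trial %in% val_trials))
}

#' Resample a clip in time by a dilation factor
#'
#' Linear interpolation stretches (`d_f > 1`) or compresses (`d_f < 1`) the
#' clip onto `round(L * d_f)` points with endpoints preserved; categorical
#' columns are resampled by nearest neighbor (class identities cannot be
#' interpolated).
#'
#' @param inputs L x N numeric matrix.
#' @param outputs Optional L x R numeric matrix resampled alongside.
#' @param d_f Dilation factor in \[0.5, 2\].
#' @param categorical Optional length-L vector (e.g. integer classes)
#'   resampled by nearest neighbor.
#' @return List with resampled `inputs`, `outputs`, `categorical`, `length`.
#' @export
resample_clip <- function(inputs, outputs = NULL, d_f, categorical = NULL) {
  if (d_f < 0.5 || d_f > 2) stop("`d_f` must lie in [0.5, 2]")
  inputs <- as.matrix(inputs)
  L <- nrow(inputs)
  L2 <- as.integer(round(L * d_f))
  if (L2 < 2) stop("resampled length would be < 2")
  grid <- seq(1, L, length.out = L2)
  lin <- function(m) apply(m, 2, function(col)
    stats::approx(seq_len(L), col, xout = grid)$y)
  out <- list(inputs = lin(inputs),
              outputs = if (!is.null(outputs)) lin(as.matrix(outputs)),
              categorical = if (!is.null(categorical)) categorical[round(grid)],
              length = L2)
  out
}

#' Assemble augmented training snippets
#'
#' Builds `n_snippets` fixed-length snippets by appending dilated/compressed
#' clips of the stream. Each clip starts at a random bin, has raw duration
#' uniform in `clip_frac` times the snippet duration (the bound applies to
#' the raw clip, before dilation), and a dilation factor uniform in
#' `c(dmin, dmax)`. A candidate clip is accepted only if no condition's share
#' of the running balance record would exceed its target share by more than
#' `tolerance`; rejected candidates are redrawn. The final clip of each
#' snippet is truncated to land exactly on `snippet_len` bins. Clips may span
#' trial boundaries (the method's purpose is to fracture trial structure);
#' set `within_trial = TRUE` to forbid it.
#'
#' Target shares are uniform over movement types present in the stream
#' (unimanual right / unimanual left / bimanual / no movement), subdivided
#' uniformly over direction quadrants (and over the no-movement subtypes).
#'
#' @param stream A `labeled_stream`.
#' @param n_snippets Number of snippets.
#' @param snippet_len Snippet length in bins (default 500, i.e. 10 s).
#' @param dmin,dmax Dilation-factor range.
#' @param clip_frac Raw clip duration range as a fraction of `snippet_len`.
#' @param tolerance Maximum excess of a condition's realized share over its
#'   target share.
#' @param within_trial Forbid clips that span trial boundaries.
#' @param max_redraws Redraws allowed per clip before giving up.
#' @param seed RNG seed.
#' @return A `snippet_set`: `inputs` (S x T x N), `vel` (S x T x 4), `ctx`
#'   (S x T), `balance` (per-condition bin counts, target shares), and
#'   `provenance` (per-snippet clip list).
#' @export
assemble_snippets <- function(stream, n_snippets, snippet_len = 500,
                              dmin = 0.5, dmax = 2, clip_frac = c(0.2, 0.8),
                              tolerance = 0.1, within_trial = FALSE,
                              max_redraws = 500, seed = 1L) {
  stopifnot(inherits(stream, "labeled_stream"))
  n_bins <- nrow(stream$inputs)
  if (n_bins < snippet_len * clip_frac[1] + 2) stop("stream too short to draw clips")
  targets <- condition_targets(stream$condition)

  counts <- stats::setNames(numeric(length(targets)), names(targets))
  N <- ncol(stream$inputs)
  inputs <- array(0, c(n_snippets, snippet_len, N))
  vel <- array(0, c(n_snippets, snippet_len, 4))
  ctx <- matrix(1L, n_snippets, snippet_len)
  provenance <- vector("list", n_snippets)

  with_seed(child_seed(seed, "snippets"), {
    for (s in seq_len(n_snippets)) {
      filled <- 0L
      clips <- list()
      while (filled < snippet_len) {
        ok <- FALSE
        for (try in seq_len(max_redraws)) {
          raw_len <- as.integer(round(stats::runif(1, clip_frac[1], clip_frac[2]) *
                                        snippet_len))
          start <- sample.int(n_bins - raw_len + 1L, 1)
          rng <- start:(start + raw_len - 1L)
          if (within_trial && length(unique(stream$trial[rng])) > 1) next
          d_f <- stats::runif(1, dmin, dmax)
          rs <- resample_clip(stream$inputs[rng, , drop = FALSE],
                              cbind(stream$vel[rng, , drop = FALSE]),
                              d_f, categorical = stream$condition[rng])
          keep <- min(rs$length, snippet_len - filled)
          add <- table(rs$categorical[seq_len(keep)])
          new_counts <- counts
          new_counts[names(add)] <- new_counts[names(add)] + add
          # the share cap is meaningful only once the record is larger than a
          # single clip; before that every clip would overshoot trivially.
          # A clip is rejected only if it contributes bins to a condition
          # whose share would exceed its cap -- clips that merely dilute an
          # already-over-cap condition are progress and stay acceptable.
          if (sum(new_counts) > 2 * snippet_len) {
            share <- new_counts / sum(new_counts)
            over <- share > targets[names(share)] + tolerance
            contributes <- names(new_counts) %in% names(add)
            if (any(over & contributes)) next
          }
          counts <- new_counts
          rows <- filled + seq_len(keep)
          inputs[s, rows, ] <- rs$inputs[seq_len(keep), ]
          vel[s, rows, ] <- rs$outputs[seq_len(keep), ]
          src <- round(seq(1, raw_len, length.out = rs$length))[seq_len(keep)]
          ctx[s, rows] <- stream$ctx[rng][src]
          clips[[length(clips) + 1]] <- data.frame(
            start = start, raw_len = raw_len, d_f = d_f, used = keep)
          filled <- filled + keep
          ok <- TRUE
          break
        }
        if (!ok) {
          stop("balancing infeasible: could not draw a clip satisfying the ",
               "balance record (rarest conditions: ",
               paste(utils::head(names(sort(counts / sum(counts) - targets)), 3),
                     collapse = ", "), ")")
        }
      }
      provenance[[s]] <- do.call(rbind, clips)
    }
  })
  structure(list(inputs = inputs, vel = vel, ctx = ctx,
                 balance = list(counts = counts, targets = targets,
                                tolerance = tolerance),
                 provenance = provenance, seed = seed,
                 snippet_len = snippet_len),
            class = "snippet_set")
}

# Uniform target share over movement types, subdivided uniformly over the
# conditions observed within each type.
condition_targets <- function(condition) {
  conds <- sort(unique(condition))
  type_of <- function(x) {
    ifelse(grepl("_delay$|^rest$", x), "no_movement",
    ifelse(grepl("^bimanual", x), "bimanual",
    ifelse(grepl("^unimanual_right", x), "unimanual_right", "unimanual_left")))
  }
  types <- type_of(conds)
  n_types <- length(unique(types))
  tgt <- numeric(length(conds))
  for (ty in unique(types)) {
    members <- types == ty
    tgt[members] <- (1 / n_types) / sum(members)
  }
  stats::setNames(tgt, conds)
}

#' Stereotyped (unaltered) training snippets
#'
#' Cuts the stream into consecutive non-overlapping snippets in task order,
#' preserving the delayed-movement trial structure — the training set the
#' augmentation method is compared against.
#'
#' @param stream A `labeled_stream`.
#' @param snippet_len Snippet length in bins.
#' @return A `snippet_set` (no balance record; provenance lists offsets).
#' @export
stereotyped_snippets <- function(stream, snippet_len = 500) {
  n_bins <- nrow(stream$inputs)
  S <- n_bins %/% snippet_len
  if (S < 1) stop("stream shorter than one snippet")
  N <- ncol(stream$inputs)
  inputs <- array(0, c(S, snippet_len, N))
  vel <- array(0, c(S, snippet_len, 4))
  ctx <- matrix(1L, S, snippet_len)
  for (s in seq_len(S)) {
    rows <- (s - 1L) * snippet_len + seq_len(snippet_len)
    inputs[s, , ] <- stream$inputs[rows, ]
    vel[s, , ] <- stream$vel[rows, ]
    ctx[s, ] <- stream$ctx[rows]
  }
  structure(list(inputs = inputs, vel = vel, ctx = ctx, balance = NULL,
                 provenance = lapply(seq_len(S), function(s)
                   data.frame(start = (s - 1L) * snippet_len + 1L,
                              raw_len = snippet_len, d_f = 1, used = snippet_len)),
                 snippet_len = snippet_len),
            class = "snippet_set")
}

#' @export
print.snippet_set <- function(x, ...) {
  d <- dim(x$inputs)
  cat(sprintf("<snippet_set> %d snippets x %d bins x %d channels\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Replay a snippet from its provenance record
#'
#' Rebuilds snippet `s` of a `snippet_set` from the source stream and the
#' recorded clip list; bit-identical to the stored snippet.
#'
#' @param snippets A `snippet_set` from [assemble_snippets()].
#' @param stream The source `labeled_stream`.
#' @param s Snippet index.
#' @return List with `inputs`, `vel`, `ctx` for the rebuilt snippet.
#' @export
replay_snippet <- function(snippets, stream, s) {
  prov <- snippets$provenance[[s]]
  T <- snippets$snippet_len
  inputs <- matrix(0, T, ncol(stream$inputs))
  vel <- matrix(0, T, 4)
  ctx <- integer(T)
  filled <- 0L
  for (i in seq_len(nrow(prov))) {
    rng <- prov$start[i]:(prov$start[i] + prov$raw_len[i] - 1L)
    rs <- resample_clip(stream$inputs[rng, , drop = FALSE],
                        stream$vel[rng, , drop = FALSE], prov$d_f[i])
    keep <- prov$used[i]
    rows <- filled + seq_len(keep)
    inputs[rows, ] <- rs$inputs[seq_len(keep), ]
    vel[rows, ] <- rs$outputs[seq_len(keep), ]
    src <- round(seq(1, prov$raw_len[i], length.out = rs$length))[seq_len(keep)]
    ctx[rows] <- stream$ctx[rng][src]
    filled <- filled + keep
  }
  list(inputs = inputs, vel = vel, ctx = ctx)
}
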