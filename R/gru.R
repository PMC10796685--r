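# Context-gated recurrent velocity decoder: a day-specific affine input
# transform, a single gated-recurrent-unit (GRU) layer, a continuous head
# producing four cursor velocities and a discrete head producing softmax
# context probabilities over {unimanual_right, unimanual_left, bimanual,
# no_movement}. The discrete output gates the velocities: a cursor only moves
# when its context class is active. Forward/backward passes are written on
# matrix ops (one BLAS call per gate per time step) and verified against
# finite-difference gradients in the test suite.

RNN_CLASSES <- c("unimanual_right", "unimanual_left", "bimanual", "no_movement")

# GRU convention: z = update gate, r = reset gate,
#   h_t = (1 - z) * h_{t-1} + z * tanh(W_h x + U_h (r * h_{t-1}) + b_h)

rnn_init <- function(n_in, hidden, n_days = 1, seed = 1L) {
  with_seed(child_seed(seed, "rnn-init"), {
    gl <- function(a, b) matrix(stats::rnorm(a * b, sd = sqrt(1 / a)), a, b)
    params <- list(
      Wz = gl(n_in, hidden), Uz = gl(hidden, hidden), bz = numeric(hidden),
      Wr = gl(n_in, hidden), Ur = gl(hidden, hidden), br = numeric(hidden),
      Wh = gl(n_in, hidden), Uh = gl(hidden, hidden), bh = numeric(hidden),
      Wv = gl(hidden, 4), bv = numeric(4),
      Wc = gl(hidden, 4), bc = numeric(4))
    for (d in seq_len(n_days)) {
      params[[paste0("A", d)]] <- diag(n_in)        # identity-initialized
      params[[paste0("a", d)]] <- numeric(n_in)     # day-specific affine
    }
    params
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass over a batch of sequences. X: B x T x N array. Returns hidden
# states and head outputs; with cache = TRUE also the gate activations needed
# for backpropagation through time.
rnn_forward <- function(params, X, day = 1, h0 = NULL, cache = FALSE) {
  dims <- dim(X); B <- dims[1]; Tn <- dims[2]; N <- dims[3]
  H <- ncol(params$Uz)
  A <- params[[paste0("A", day)]]; ab <- params[[paste0("a", day)]]
  h <- if (is.null(h0)) matrix(0, B, H) else h0
  hs <- array(0, c(B, Tn, H))
  xs <- if (cache) array(0, c(B, Tn, N)) else NULL
  zs <- rs <- cs <- if (cache) array(0, c(B, Tn, H)) else NULL
  for (t in seq_len(Tn)) {
    x <- matrix(X[, t, ], B, N) %*% A
    x <- sweep(x, 2, ab, `+`)
    z <- sigmoid(sweep(x %*% params$Wz + h %*% params$Uz, 2, params$bz, `+`))
    r <- sigmoid(sweep(x %*% params$Wr + h %*% params$Ur, 2, params$br, `+`))
    cand <- tanh(sweep(x %*% params$Wh + (r * h) %*% params$Uh, 2, params$bh, `+`))
    h_new <- (1 - z) * h + z * cand
    hs[, t, ] <- h_new
    if (cache) { xs[, t, ] <- x; zs[, t, ] <- z; rs[, t, ] <- r; cs[, t, ] <- cand }
    h <- h_new
  }
  hs_flat <- matrix(aperm(hs, c(1, 2, 3)), B * Tn, H)
  vel <- sweep(hs_flat %*% params$Wv, 2, params$bv, `+`)
  logits <- sweep(hs_flat %*% params$Wc, 2, params$bc, `+`)
  out <- list(h_last = h, hs = hs, vel = array(vel, c(B, Tn, 4)),
              logits = array(logits, c(B, Tn, 4)))
  if (cache) out[c("xs", "zs", "rs", "cs")] <- list(xs, zs, rs, cs)
  out
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

# Loss and gradients for one batch. vel_t: B x T x 4; ctx_t: B x T integer in
# 1..4. Loss = mean squared velocity error + ce_weight * mean cross-entropy +
# l2 * sum of squared weights.
rnn_loss_grad <- function(params, X, vel_t, ctx_t, day = 1, ce_weight = 1,
                          l2 = 1e-5) {
  fw <- rnn_forward(params, X, day = day, cache = TRUE)
  dims <- dim(X); B <- dims[1]; Tn <- dims[2]; N <- dims[3]
  H <- ncol(params$Uz); M <- B * Tn
  hs_flat <- matrix(fw$hs, M, H)

  vel_flat <- matrix(fw$vel, M, 4)
  velt_flat <- matrix(vel_t, M, 4)
  err <- vel_flat - velt_flat
  mse <- mean(err^2)
  g_vel <- 2 * err / (M * 4)

  logit_flat <- matrix(fw$logits, M, 4)
  p <- softmax_rows(logit_flat)
  ci <- as.integer(ctx_t)
  pick <- cbind(seq_len(M), ci)
  ce <- -mean(log(pmax(p[pick], 1e-12)))
  g_logit <- p
  g_logit[pick] <- g_logit[pick] - 1
  g_logit <- ce_weight * g_logit / M

  if (!is.finite(mse) || !is.finite(ce)) stop("RNN training diverged (non-finite loss)")

  w_names <- grep("^(W|U|A)", names(params), value = TRUE)
  l2_term <- l2 * sum(vapply(w_names, function(nm) sum(params[[nm]]^2), numeric(1)))

  grads <- lapply(params, function(p) p * 0)
  grads$Wv <- crossprod(hs_flat, g_vel); grads$bv <- colSums(g_vel)
  grads$Wc <- crossprod(hs_flat, g_logit); grads$bc <- colSums(g_logit)

  g_hs <- g_vel %*% t(params$Wv) + g_logit %*% t(params$Wc)
  g_hs <- array(g_hs, c(B, Tn, H))

  Ak <- paste0("A", day); ak <- paste0("a", day)
  g_h_next <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    g_h <- matrix(g_hs[, t, ], B, H) + g_h_next
    h_prev <- if (t == 1) matrix(0, B, H) else matrix(fw$hs[, t - 1, ], B, H)
    z <- matrix(fw$zs[, t, ], B, H); r <- matrix(fw$rs[, t, ], B, H)
    cand <- matrix(fw$cs[, t, ], B, H); x <- matrix(fw$xs[, t, ], B, N)

    g_cand <- g_h * z
    g_z <- g_h * (cand - h_prev)
    g_h_prev <- g_h * (1 - z)

    g_pre_c <- g_cand * (1 - cand^2)              # tanh'
    grads$Wh <- grads$Wh + crossprod(x, g_pre_c)
    grads$Uh <- grads$Uh + crossprod(r * h_prev, g_pre_c)
    grads$bh <- grads$bh + colSums(g_pre_c)
    g_rh <- g_pre_c %*% t(params$Uh)
    g_r <- g_rh * h_prev
    g_h_prev <- g_h_prev + g_rh * r

    g_pre_z <- g_z * z * (1 - z)                  # sigmoid'
    grads$Wz <- grads$Wz + crossprod(x, g_pre_z)
    grads$Uz <- grads$Uz + crossprod(h_prev, g_pre_z)
    grads$bz <- grads$bz + colSums(g_pre_z)
    g_h_prev <- g_h_prev + g_pre_z %*% t(params$Uz)

    g_pre_r <- g_r * r * (1 - r)
    grads$Wr <- grads$Wr + crossprod(x, g_pre_r)
    grads$Ur <- grads$Ur + crossprod(h_prev, g_pre_r)
    grads$br <- grads$br + colSums(g_pre_r)
    g_h_prev <- g_h_prev + g_pre_r %*% t(params$Ur)

    g_x <- g_pre_c %*% t(params$Wh) + g_pre_z %*% t(params$Wz) +
      g_pre_r %*% t(params$Wr)
    grads[[Ak]] <- grads[[Ak]] + crossprod(matrix(X[, t, ], B, N), g_x)
    grads[[ak]] <- grads[[ak]] + colSums(g_x)

    g_h_next <- g_h_prev
  }
  for (nm in w_names) grads[[nm]] <- grads[[nm]] + 2 * l2 * params[[nm]]
  list(loss = mse + ce_weight * ce + l2_term, mse = mse, ce = ce,
       grads = grads)
}

#' Default GRU decoder training configuration
#'
#' @param hidden GRU width (512 at full scale; smaller for desk-scale runs).
#' @param lr Adam learning rate.
#' @param batch_size Snippets per training batch.
#' @param n_batches Number of training batches (steps).
#' @param l2 L2 penalty on all weight matrices.
#' @param ce_weight Weight of the cross-entropy context loss relative to the
#'   squared velocity error.
#' @param input_noise_sd SD of i.i.d. Gaussian noise added to inputs each
#'   step (training-time augmentation).
#' @param mean_drift_sd SD of the slowly varying per-channel offset added
#'   across a snippet (random constant per snippet here; emulates slow mean
#'   drift in the recordings).
#' @param seed RNG seed.
#' @return Named list of settings for [train_rnn()].
#' @export
rnn_config <- function(hidden = 512, lr = 2e-3, batch_size = 8,
                       n_batches = 300, l2 = 1e-5, ce_weight = 1,
                       input_noise_sd = 0.2, mean_drift_sd = 0.1,
                       seed = 1L) {
  as.list(environment())
}

#' Train the context-gated GRU decoder
#'
#' Trains on a snippet set (see [assemble_snippets()] or
#' [stereotyped_snippets()]): inputs are z-scored firing-rate sequences, and
#' the loss is the sum of a squared error on the four cursor velocities, a
#' cross-entropy on the discrete movement-context classes, and an L2 weight
#' penalty. Optional input-noise and mean-drift augmentations are applied to
#' each training batch. Deterministic given the config seed.
#'
#' @param snippets A `snippet_set`.
#' @param config See [rnn_config()].
#' @param val_snippets Optional held-out `snippet_set`; validation loss is
#'   recorded every 25 batches.
#' @param verbose Print progress.
#' @return A `bci_rnn` model.
#' @export
train_rnn <- function(snippets, config = rnn_config(), val_snippets = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(snippets, "snippet_set"))
  X <- snippets$inputs; Yv <- snippets$vel; Yc <- snippets$ctx
  S <- dim(X)[1]; N <- dim(X)[3]
  params <- rnn_init(N, config$hidden, n_days = 1, seed = config$seed)
  opt <- adam_init(params)
  log <- list()
  with_seed(child_seed(config$seed, "rnn-train"), {
    for (step in seq_len(config$n_batches)) {
      idx <- sample(S, min(config$batch_size, S))
      xb <- X[idx, , , drop = FALSE]
      if (config$input_noise_sd > 0) {
        xb <- xb + array(stats::rnorm(length(xb), sd = config$input_noise_sd),
                         dim(xb))
      }
      if (config$mean_drift_sd > 0) {
        drift <- matrix(stats::rnorm(length(idx) * N, sd = config$mean_drift_sd),
                        length(idx), N)
        xb <- xb + aperm(array(drift, c(length(idx), N, dim(xb)[2])), c(1, 3, 2))
      }
      lg <- rnn_loss_grad(params, xb, Yv[idx, , , drop = FALSE],
                          Yc[idx, , drop = FALSE],
                          ce_weight = config$ce_weight, l2 = config$l2)
      params <- adam_update(params, lg$grads, opt, config$lr, step)
      if (step %% 25 == 0) {
        vl <- NA_real_
        if (!is.null(val_snippets)) {
          vl <- rnn_eval_loss(params, val_snippets, config)
        }
        log[[length(log) + 1]] <- data.frame(step = step, train_loss = lg$loss,
                                             mse = lg$mse, ce = lg$ce,
                                             val_loss = vl)
        if (verbose) message(sprintf("step %d loss %.4f (mse %.4f ce %.4f) val %.4f",
                                     step, lg$loss, lg$mse, lg$ce, vl))
      }
    }
  })
  structure(list(params = params, config = config, n_in = N,
                 classes = RNN_CLASSES,
                 log = do.call(rbind, log)),
            class = "bci_rnn")
}

rnn_eval_loss <- function(params, snippets, config) {
  lg <- rnn_loss_grad(params, snippets$inputs, snippets$vel, snippets$ctx,
                      ce_weight = config$ce_weight, l2 = 0)
  lg$loss
}

#' One 20-ms inference step of the GRU decoder
#'
#' Applies the day-specific affine transform, advances the GRU by one bin,
#' and gates the velocity outputs by the argmax context class: the left
#' cursor's velocity is zeroed unless the context is unimanual-left or
#' bimanual (right cursor analogous); no-movement zeroes both.
#'
#' @param model A `bci_rnn`.
#' @param bin_vector Length-N z-scored firing-rate bin.
#' @param state Hidden state from the previous step (`NULL` to start).
#' @param day Day index of the affine input transform.
#' @return List: `velocity` (gated, length 4), `raw_velocity`, `context`
#'   (class name), `probs`, `state`.
#' @export
rnn_step <- function(model, bin_vector, state = NULL, day = 1) {
  if (!paste0("A", day) %in% names(model$params)) stop("unknown day id: ", day)
  X <- array(bin_vector, c(1, 1, model$n_in))
  h0 <- if (is.null(state)) NULL else state
  fw <- rnn_forward(model$params, X, day = day, h0 = h0)
  probs <- drop(softmax_rows(matrix(fw$logits, 1, 4)))
  names(probs) <- model$classes
  cls <- model$classes[which.max(probs)]
  raw <- drop(fw$vel)
  vel <- gate_velocity(raw, cls)
  list(velocity = vel, raw_velocity = raw, context = cls, probs = probs,
       state = fw$h_last)
}

gate_velocity <- function(v, context) {
  if (context %in% c("unimanual_left", "no_movement")) v[1:2] <- 0
  if (context %in% c("unimanual_right", "no_movement")) v[3:4] <- 0
  v
}

#' Decode a sequence with the GRU, with context gating
#'
#' Equivalent to threading [rnn_step()] over the rows of `features` from a
#' zero hidden state.
#'
#' @param object A `bci_rnn`.
#' @param newdata bins x channels matrix (a sequence), or a B x T x N array
#'   of snippets.
#' @param day Day index.
#' @param gated Apply context gating to the returned velocities.
#' @param ... Unused.
#' @return For matrix input: list `velocity` (bins x 4), `context`, `probs`.
#'   For array input the same with a leading snippet dimension.
#' @export
predict.bci_rnn <- function(object, newdata, day = 1, gated = TRUE, ...) {
  arr <- if (length(dim(newdata)) == 3) newdata else
    array(as.matrix(newdata), c(1, dim(newdata)))
  fw <- rnn_forward(object$params, arr, day = day)
  B <- dim(arr)[1]; Tn <- dim(arr)[2]
  p <- softmax_rows(matrix(fw$logits, B * Tn, 4))
  cls_i <- max.col(p)
  vel <- matrix(fw$vel, B * Tn, 4)
  if (gated) {
    vel[cls_i %in% c(2, 4), 1:2] <- 0
    vel[cls_i %in% c(1, 4), 3:4] <- 0
  }
  if (length(dim(newdata)) == 3) {
    list(velocity = array(vel, c(B, Tn, 4)),
         context = array(object$classes[cls_i], c(B, Tn)),
         probs = array(p, c(B, Tn, 4)))
  } else {
    list(velocity = vel, context = object$classes[cls_i], probs = p)
  }
}
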