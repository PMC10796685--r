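# End-to-end experiment runners: the correlation x laterality simulation
# sweep comparing ridge and FFN decoders, the augmentation (raw vs altered
# snippets) GRU comparison with simulated closed-loop evaluation, and the
# reanalysis entry point for deposited sessions.

#' Decoder comparison across tuning correlation and laterality size
#'
#' For every (rho, lat_scale) grid cell: sample a population, generate a
#' balanced unimanual dataset, calibrate the noise to the fSNR target, train
#' a ridge decoder and an FFN on identical folds, and record held-out
#' decoding performance (mean Pearson r over the four velocity outputs) and
#' per-decoder cursor jitter. A held-out test split (balanced over trial
#' types) is used for all reported numbers.
#'
#' @param rhos Directional tuning correlations between the hands to sweep.
#' @param lat_scales Laterality dimension sizes to sweep.
#' @param n_per_hand Trials per hand per cell.
#' @param n_channels Channels per population.
#' @param fsnr_target Per-hand fSNR target for noise calibration.
#' @param ffn Settings for [train_ffn()] (list).
#' @param test_fraction Held-out fraction of trials.
#' @param seed RNG seed.
#' @return A `sweep_result` with matrices (`rho` x `lat_scale`) `ridge_r`,
#'   `ffn_r`, `ridge_jitter`, `ffn_jitter`, and per-cell sigma.
#' @export
run_laterality_sweep <- function(rhos = c(0, 0.25, 0.5, 0.75, 0.9, 1),
                                 lat_scales = c(0, 0.25, 0.5, 1),
                                 n_per_hand = 250, n_channels = 192,
                                 fsnr_target = 2,
                                 ffn = list(hidden = 256, epochs = 60),
                                 test_fraction = 0.2, seed = 1L) {
  dims <- c(length(rhos), length(lat_scales))
  dn <- list(rho = as.character(rhos), lat_scale = as.character(lat_scales))
  out <- list(ridge_r = matrix(NA_real_, dims[1], dims[2], dimnames = dn),
              ffn_r = matrix(NA_real_, dims[1], dims[2], dimnames = dn),
              ridge_jitter = matrix(NA_real_, dims[1], dims[2], dimnames = dn),
              ffn_jitter = matrix(NA_real_, dims[1], dims[2], dimnames = dn),
              sigma = matrix(NA_real_, dims[1], dims[2], dimnames = dn))
  for (i in seq_along(rhos)) for (j in seq_along(lat_scales)) {
    cell <- tryCatch(
      sweep_cell(rhos[i], lat_scales[j], n_per_hand, n_channels, fsnr_target,
                 ffn, test_fraction, seed),
      error = function(e) stop(sprintf("sweep cell (rho=%g, lat=%g) failed: %s",
                                       rhos[i], lat_scales[j], conditionMessage(e)),
                               call. = FALSE))
    out$ridge_r[i, j] <- cell$ridge_r
    out$ffn_r[i, j] <- cell$ffn_r
    out$ridge_jitter[i, j] <- cell$ridge_jitter
    out$ffn_jitter[i, j] <- cell$ffn_jitter
    out$sigma[i, j] <- cell$sigma
  }
  structure(c(out, list(rhos = rhos, lat_scales = lat_scales,
                        n_per_hand = n_per_hand, seed = seed)),
            class = "sweep_result")
}

sweep_cell <- function(rho, lat, n_per_hand, n_channels, fsnr_target, ffn,
                       test_fraction, seed, remove_lat = FALSE) {
  pop <- sample_population(n_channels, rho_x = rho, rho_y = rho,
                           lat_scale = lat, seed = child_seed(seed, "pop", rho, lat))
  ds <- generate_unimanual_dataset(pop, n_per_hand = n_per_hand,
                                   seed = child_seed(seed, "ds", rho, lat))
  nm <- calibrate_sigma(pop, ds, target_fsnr = fsnr_target,
                        seed = child_seed(seed, "cal", rho, lat))
  ds$rates <- add_noise_and_clip(ds$rates, nm, seed = child_seed(seed, "noise", rho, lat))
  ds <- zscore_session(remove_block_means(ds))
  if (remove_lat) ds <- remove_laterality(ds)

  lb <- ds$labels
  X <- ds$rates
  Y <- as.matrix(lb[, c("v_rx", "v_ry", "v_lx", "v_ly")])
  # balanced held-out test split over trial types
  test_trials <- unlist(lapply(split(ds$trial_table$trial, ds$trial_table$type),
    function(t) utils::tail(t, round(test_fraction * length(t)))))
  te <- lb$trial %in% test_trials

  ridge <- train_ridge(X[!te, ], Y[!te, ], groups = lb$context[!te],
                       seed = child_seed(seed, "ridge"))
  ffn_model <- do.call(train_ffn, c(list(features = X[!te, ], targets = Y[!te, ],
                                         seed = child_seed(seed, "ffn")), ffn))
  d_ridge <- decode_offline(ridge, X[te, ], Y[te, ])
  d_ffn <- decode_offline(ffn_model, X[te, ], Y[te, ])
  active <- ifelse(lb$context[te] == "unimanual_right", "right", "left")
  list(ridge_r = mean(d_ridge$r), ffn_r = mean(d_ffn$r),
       ridge_jitter = mean(cursor_jitter(d_ridge$predictions, active)),
       ffn_jitter = mean(cursor_jitter(d_ffn$predictions, active)),
       sigma = nm$sigma, pop = pop, session = ds, test = te,
       ridge = ridge, ffn = ffn_model)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("ridge held-out r:\n"); print(round(x$ridge_r, 3))
  cat("FFN held-out r:\n"); print(round(x$ffn_r, 3))
  cat("jitter (ridge / FFN):\n")
  print(round(x$ridge_jitter, 2)); print(round(x$ffn_jitter, 2))
  invisible(x)
}

#' Raw vs altered training data for the GRU decoder
#'
#' Trains two GRU decoders on the same source session: `rawRNN` on
#' stereotyped consecutive snippets that preserve the delay-move-idle trial
#' structure, and `altRNN` on snippets assembled from dilated/compressed,
#' shuffled clips. Reports offline held-out decoding performance on
#' stereotyped validation data (where the raw decoder's overlearning of the
#' task structure pays off) and simulated closed-loop performance (where it
#' does not).
#'
#' @param pop A `sim_population` (defaults to a moderately correlated one).
#' @param n_per_type Open-loop trials per movement type.
#' @param sigma Noise SD in Hz (calibrated value for the default population
#'   scale).
#' @param snippet_len Snippet length in bins.
#' @param n_snippets Augmented snippets to assemble.
#' @param rnn Settings passed to [rnn_config()].
#' @param n_trials Closed-loop trials per decoder.
#' @param types Closed-loop trial types.
#' @param config Closed-loop [task_config()].
#' @param seed RNG seed.
#' @return List with `offline` (per-decoder held-out r), `closedloop`
#'   (per-decoder trial summaries), and the trained models.
#' @export
run_augmentation_comparison <- function(pop = NULL, n_per_type = 30,
                                        sigma = 5, snippet_len = 250,
                                        n_snippets = 60,
                                        rnn = list(hidden = 128),
                                        n_trials = 24,
                                        types = c("unimanual_right",
                                                  "unimanual_left"),
                                        config = task_config(),
                                        seed = 1L) {
  if (is.null(pop)) {
    pop <- sample_population(96, rho_x = 0.5, rho_y = 0.5, lat_scale = 1,
                             seed = child_seed(seed, "aug-pop"))
  }
  nm <- noise_model(sigma)
  sess <- generate_delayed_session(pop, n_per_type = n_per_type,
                                   types = types,
                                   seed = child_seed(seed, "aug-sess"))
  sess$rates <- add_noise_and_clip(sess$rates, nm, seed = child_seed(seed, "aug-noise"))
  # z-scoring doubles as (single-block) mean removal; its statistics are kept
  # on the raw-rate scale so that online bins can be transformed identically
  sess <- zscore_session(sess)
  zstats <- sess$preprocessing$zscore_stats

  stream <- label_stream(sess)
  pools <- split_pools(stream, validation_fraction = 0.15,
                       seed = child_seed(seed, "aug-split"))
  raw_train <- stereotyped_snippets(pools$train, snippet_len)
  raw_val <- stereotyped_snippets(pools$validation, snippet_len)
  alt_train <- assemble_snippets(pools$train, n_snippets, snippet_len,
                                 seed = child_seed(seed, "aug-snip"))

  cfg <- do.call(rnn_config, c(rnn, list(seed = child_seed(seed, "rnn"))))
  raw_rnn <- train_rnn(raw_train, cfg, val_snippets = raw_val)
  alt_rnn <- train_rnn(alt_train, cfg, val_snippets = raw_val)

  offline_r <- function(model) {
    pr <- stats::predict(model, raw_val$inputs, gated = FALSE)
    mean(vapply(1:4, function(j)
      safe_cor(as.vector(pr$velocity[, , j]), as.vector(raw_val$vel[, , j])),
      numeric(1)), na.rm = TRUE)
  }
  user <- sim_user(pop)
  clo <- function(model) {
    run_trials(model, user, noise = nm, zstats = zstats, n_trials = n_trials,
               types = types, config = config, seed = child_seed(seed, "cl"))
  }
  raw_cl <- clo(raw_rnn); alt_cl <- clo(alt_rnn)
  list(offline = c(rawRNN = offline_r(raw_rnn), altRNN = offline_r(alt_rnn)),
       closedloop = list(rawRNN = raw_cl, altRNN = alt_cl),
       summary = data.frame(
         decoder = c("rawRNN", "altRNN"),
         offline_r = c(offline_r(raw_rnn), offline_r(alt_rnn)),
         success_rate = c(mean(raw_cl$trials$success), mean(alt_cl$trials$success)),
         mean_tta = c(mean(raw_cl$trials$tta), mean(alt_cl$trials$tta))),
       models = list(rawRNN = raw_rnn, altRNN = alt_rnn),
       session = sess, seed = seed)
}

#' Reanalyze deposited sessions
#'
#' Runs the tuning pipeline (cross-validated encoding fits, suppression
#' ratios, unimanual-to-bimanual tuning correlations, and dPCA marginalized
#' variance) on sessions stored on disk in the package's session layout (see
#' [write_session()]): a directory containing one sub-directory per session,
#' each with `rates.csv`, `labels.csv`, `trials.csv` and `meta.json`. The
#' archive is never downloaded automatically.
#'
#' @param path Directory of session sub-directories.
#' @param k Folds for the encoding fits.
#' @param seed RNG seed.
#' @return Data frame, one row per session: suppression ratios and tuning
#'   correlations per hand, dPCA laterality/direction fractions. Schema is
#'   identical to the synthetic tuning report.
#' @export
reanalyze_deposited <- function(path, k = 3, seed = 1L) {
  if (!dir.exists(path)) {
    stop("session archive not found at '", path, "'. Expected a directory ",
         "with one sub-directory per session, each containing rates.csv, ",
         "labels.csv, trials.csv and meta.json as written by write_session(). ",
         "Deposited data must be downloaded manually and converted first.")
  }
  dirs <- list.dirs(path, recursive = FALSE)
  if (length(dirs) == 0) stop("no session sub-directories under '", path, "'")
  do.call(rbind, lapply(dirs, function(d) {
    sess <- read_session(d)
    cbind(session = basename(d), tuning_report(sess, k = k, seed = seed))
  }))
}

#' Tuning report for one session
#'
#' The per-session statistics block shared by the synthetic pipeline and
#' [reanalyze_deposited()]. Session-level reports are typically averaged
#' over block-set replicates, as population tuning statistics are in
#' practice.
#'
#' @param session A `bci_session` containing unimanual and bimanual trials.
#' @param k Folds.
#' @param n_repeats Fold-assignment repeats averaged over (the cv estimators
#'   are unbiased but fold-noisy on small sessions).
#' @param seed RNG seed.
#' @return One-row data frame: `suppression_right`, `suppression_left`,
#'   `corr_right`, `corr_left` (uni-bi tuning correlations averaged over
#'   x/y), `dpca_laterality`, `dpca_direction` (variance fractions).
#' @export
tuning_report <- function(session, k = 3, n_repeats = 5, seed = 1L) {
  if (!session$preprocessing$block_means_removed) {
    session <- remove_block_means(session)
  }
  reps <- lapply(seq_len(n_repeats), function(rs) {
    f_ur <- fit_encoding_cv(session, "unimanual_right", k = k, seed = child_seed(seed, rs))
    f_ul <- fit_encoding_cv(session, "unimanual_left", k = k, seed = child_seed(seed, rs))
    f_bi <- fit_encoding_cv(session, "bimanual", k = k, seed = child_seed(seed, rs))
    c(sup_r = suppression_ratio(f_bi, f_ur, "right"),
      sup_l = suppression_ratio(f_bi, f_ul, "left"),
      cor_r = mean(c(cv_vector_stats(f_ur, f_bi, c("rx", "rx"))$correlation,
                     cv_vector_stats(f_ur, f_bi, c("ry", "ry"))$correlation)),
      cor_l = mean(c(cv_vector_stats(f_ul, f_bi, c("lx", "lx"))$correlation,
                     cv_vector_stats(f_ul, f_bi, c("ly", "ly"))$correlation)))
  })
  m <- colMeans(do.call(rbind, reps))
  mv <- dpca_marginal_variance(zscore_session(session), split_seed = seed)
  data.frame(suppression_right = m[["sup_r"]], suppression_left = m[["sup_l"]],
             corr_right = m[["cor_r"]], corr_left = m[["cor_l"]],
             dpca_laterality = mv$fraction[["laterality"]],
             dpca_direction = mv$fraction[["direction"]])
}
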