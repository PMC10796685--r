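# Build a tiny session by hand so FVAF values can be verified against
# hand-computed sums of squares.
manual_session <- function(trial_means, quadrants, hand = "right") {
  n_trials <- length(trial_means)
  bins <- 20
  wedge <- c(1, 3, 5, 7)[quadrants]  # wedge w lies in quadrant ceiling(w/2)
  ang <- (wedge - 0.5) * pi / 4
  idx <- rep(seq_len(n_trials), each = bins)
  labels <- data.frame(
    trial = idx, t_since_go = rep(0.3 + (seq_len(bins) - 0.5) * 0.02, n_trials),
    epoch = "move",
    context = if (hand == "right") "unimanual_right" else "unimanual_left",
    d_rx = if (hand == "right") cos(ang)[idx] else 0,
    d_ry = if (hand == "right") sin(ang)[idx] else 0,
    d_lx = if (hand == "left") cos(ang)[idx] else 0,
    d_ly = if (hand == "left") sin(ang)[idx] else 0)
  labels[, c("v_rx", "v_ry", "v_lx", "v_ly")] <- 0
  trial_table <- data.frame(trial = seq_len(n_trials),
                            type = labels$context[1],
                            wedge_r = if (hand == "right") wedge else NA,
                            wedge_l = if (hand == "left") wedge else NA,
                            n_bins = bins,
                            start_bin = (seq_len(n_trials) - 1) * bins + 1)
  rates <- matrix(trial_means[idx], ncol = 1)
  bci_session(rates, labels, trial_table)
}

test_that("FVAF matches hand computation", {
  # trials 1,2 in quadrant 1 and 3,4 in quadrant 2 with means 1,2,3,4:
  # SS_total = 5, SS_dir = 4, FVAF = 0.8
  s <- manual_session(c(1, 2, 3, 4), c(1, 1, 2, 2))
  et <- electrode_tuning(s, "unimanual_right")
  expect_equal(et$fvaf, 0.8)
  # means 1,1,3,3: within-group variance zero, FVAF = 1
  s2 <- manual_session(c(1, 1, 3, 3), c(1, 1, 2, 2))
  expect_equal(electrode_tuning(s2, "unimanual_right")$fvaf, 1)
  # identical rates across quadrants: zero total variance -> NA
  s3 <- manual_session(c(2, 2, 2, 2), c(1, 1, 2, 2))
  expect_true(is.na(electrode_tuning(s3, "unimanual_right")$fvaf))
})

test_that("strongly tuned channels are detected, untuned are not", {
  pop <- fix_pop()
  ds <- generate_unimanual_dataset(pop, n_per_hand = 40, seed = 71)
  ds$rates <- add_noise_and_clip(ds$rates, noise_model(2), seed = 72)
  et <- electrode_tuning(ds, "unimanual_right")
  expect_gt(mean(et$tuned), 0.5)        # tuned population, low noise
  expect_true(all(et$fvaf >= 0 & et$fvaf <= 1, na.rm = TRUE))
  # pure-noise channels are almost never flagged at p < 1e-5
  ds$rates <- matrix(rnorm(length(ds$rates)), nrow(ds$rates))
  et0 <- electrode_tuning(ds, "unimanual_right")
  expect_lt(mean(et0$tuned), 0.05)
})

test_that("bimanual grouping by one hand ignores the other hand", {
  sess <- fix_delayed()
  et_r <- electrode_tuning(sess, "bimanual", hand = "right")
  et_l <- electrode_tuning(sess, "bimanual", hand = "left")
  expect_equal(nrow(et_r), ncol(sess$rates))
  expect_false(isTRUE(all.equal(et_r$fvaf, et_l$fvaf)))
  expect_error(electrode_tuning(sess, "bimanual"), "hand")
})

test_that("PCA view separates unimanual left from right trials", {
  pop <- fix_pop()
  ds <- generate_unimanual_dataset(pop, n_per_hand = 32, seed = 73)
  ds$rates <- add_noise_and_clip(ds$rates, noise_model(3), seed = 74)
  ds <- zscore_session(remove_block_means(ds))
  pv <- pca_laterality_view(ds)
  expect_equal(dim(pv$scores), c(64L, 2L))
  # nearest-centroid classification in the top-2 PCs
  right <- pv$trial_type == "unimanual_right"
  cen_r <- colMeans(pv$scores[right, ]); cen_l <- colMeans(pv$scores[!right, ])
  d_r <- sqrt(colSums((t(pv$scores) - cen_r)^2))
  d_l <- sqrt(colSums((t(pv$scores) - cen_l)^2))
  acc <- mean((d_r < d_l) == right)
  expect_gt(acc, 0.95)
  # duplicated trials map to identical scores
  ds2 <- ds
  n <- nrow(ds$rates)
  ds2$rates <- rbind(ds$rates, ds$rates)
  ds2$labels <- rbind(ds$labels,
                      transform(ds$labels, trial = trial + max(trial)))
  tt2 <- ds$trial_table
  tt2$trial <- tt2$trial + max(tt2$trial)
  ds2$trial_table <- rbind(ds$trial_table, tt2)
  pv2 <- pca_laterality_view(ds2)
  half <- nrow(ds$trial_table)
  expect_equal(pv2$scores[seq_len(half), ], pv2$scores[half + seq_len(half), ],
               tolerance = 1e-9)
})
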