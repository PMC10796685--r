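test_that("noiseless encoding fits recover the generating coefficients", {
  pop <- fix_pop()
  ds <- remove_block_means(generate_unimanual_dataset(pop, n_per_hand = 40,
                                                      seed = 31))
  fit <- fit_encoding_cv(ds, "unimanual_right", k = 5)
  expect_equal(fit$predictors, c("intercept", "rx", "ry"))
  pooled <- Reduce(`+`, fit$fold_coeffs) / fit$k
  expect_gt(cor(pooled[, "rx"], pop$tuning_uni[, "rx"]), 0.999)
  expect_gt(cor(pooled[, "ry"], pop$tuning_uni[, "ry"]), 0.999)
  # noise-free: cv magnitude equals the plain column norm
  cs <- cv_vector_stats(fit, column = "rx")
  expect_equal(cs$magnitude, sqrt(sum(pop$tuning_uni[, "rx"]^2)),
               tolerance = 1e-6)
  # self-correlation 1; against negated fit, -1
  neg <- fit
  neg$fold_coeffs <- lapply(fit$fold_coeffs, function(m) -m)
  expect_equal(cv_vector_stats(fit, fit, "rx")$correlation, 1, tolerance = 1e-9)
  expect_equal(cv_vector_stats(fit, neg, "rx")$correlation, -1, tolerance = 1e-9)
})

test_that("intercept column equals the mean rate when velocity is zero", {
  pop <- sample_population(24, lat_scale = 0, seed = 32)
  sess <- generate_unimanual_dataset(pop, n_per_hand = 8, seed = 33)
  sess$labels[, c("d_rx", "d_ry", "d_lx", "d_ly")] <- 0
  sess$rates <- encode_rates(pop, sess$labels)
  fit <- fit_encoding_cv(sess, NULL, k = 2, seed = 1)
  pooled <- Reduce(`+`, fit$fold_coeffs) / fit$k
  expect_equal(unname(pooled[, "intercept"]), unname(colMeans(sess$rates)),
               tolerance = 1e-8)
})

test_that("cv squared-norm estimator is unbiased where the naive one is not", {
  # oracle: fold estimates = truth + i.i.d. noise; the naive squared norm of
  # the fold mean is biased upward by noise variance / k * dim
  set.seed(7)
  n_ch <- 50; k <- 5
  truth <- rnorm(n_ch); truth <- truth * 5 / sqrt(sum(truth^2))
  sd_noise <- 0.4
  reps <- replicate(500, {
    folds <- lapply(1:k, function(i) truth + rnorm(n_ch, sd = sd_noise))
    fit <- structure(list(
      fold_coeffs = lapply(folds, function(v) matrix(v, ncol = 1,
                                                     dimnames = list(NULL, "rx"))),
      predictors = "rx", k = k, n_channels = n_ch), class = "cv_fit")
    pooled <- Reduce(`+`, folds) / k
    c(cv = cv_vector_stats(fit, column = "rx")$sq_norm,
      naive = sum(pooled^2))
  })
  se_cv <- sd(reps["cv", ]) / sqrt(ncol(reps))
  expect_lt(abs(mean(reps["cv", ]) - 25), 2 * se_cv + 1e-9)
  expected_bias <- n_ch * sd_noise^2 / k
  expect_equal(mean(reps["naive", ]) - 25, expected_bias, tolerance = 0.2)
  # the naive estimator exceeds the cv estimator on the same draws
  expect_gt(mean(reps["naive", ] - reps["cv", ]), 0)
})

test_that("suppression ratio: identity, permutation invariance, recovery", {
  pop <- fix_pop()
  ds <- remove_block_means(fix_delayed())
  f_ul <- fit_encoding_cv(ds, "unimanual_left", k = 3, seed = 1)
  f_bi <- fit_encoding_cv(ds, "bimanual", k = 3, seed = 1)
  expect_equal(suppression_ratio(f_ul, f_ul, "left"), 1, tolerance = 1e-9)
  # noiseless recovery of the programmed 0.66 left-hand suppression
  expect_equal(suppression_ratio(f_bi, f_ul, "left"), 0.66, tolerance = 1e-3)
  # channel permutation leaves the ratio unchanged
  perm <- sample(pop$n_channels)
  f_ul_p <- f_ul; f_bi_p <- f_bi
  f_ul_p$fold_coeffs <- lapply(f_ul$fold_coeffs, function(m) m[perm, ])
  f_bi_p$fold_coeffs <- lapply(f_bi$fold_coeffs, function(m) m[perm, ])
  expect_equal(suppression_ratio(f_bi_p, f_ul_p, "left"),
               suppression_ratio(f_bi, f_ul, "left"))
})

test_that("pooled OLS estimates do not depend on the fold assignment", {
  # noiseless data: every fold recovers the same coefficients, so pooled
  # estimates are invariant to how trials are dealt to folds
  pop <- sample_population(16, seed = 35)
  ds <- generate_unimanual_dataset(pop, n_per_hand = 16, seed = 36)
  fit1 <- fit_encoding_cv(ds, "unimanual_right", k = 2, seed = 5)
  fit2 <- fit_encoding_cv(ds, "unimanual_right", k = 2, seed = 99)
  p1 <- Reduce(`+`, fit1$fold_coeffs) / 2
  p2 <- Reduce(`+`, fit2$fold_coeffs) / 2
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("laterality removal zeroes the refitted laterality coefficients", {
  pop <- fix_pop()
  ds <- remove_block_means(generate_unimanual_dataset(pop, n_per_hand = 32,
                                                      seed = 37))
  removed <- remove_laterality(ds)
  refit <- fit_encoding_cv(removed, NULL, k = 3, with_laterality = TRUE)
  b_new <- Reduce(`+`, bimanbci:::fold_column(refit, "lat")) / refit$k
  b_old <- pop$laterality
  expect_lt(sqrt(sum(b_new^2)), 1e-6 * sqrt(sum(b_old^2)))
  # a session without laterality is (nearly) untouched
  pop0 <- sample_population(32, lat_scale = 0, seed = 38)
  ds0 <- remove_block_means(
    generate_unimanual_dataset(pop0, n_per_hand = 16, seed = 39))
  ds0n <- ds0
  ds0n$rates <- ds0$rates + matrix(rnorm(length(ds0$rates), sd = 0.5),
                                   nrow(ds0$rates))
  out <- remove_laterality(ds0n)
  # only a noise-fit direction is removed; signal is preserved
  expect_equal(out$rates, ds0n$rates, tolerance = 0.2)
})

test_that("linear decoding is unaffected by laterality removal", {
  pop <- sample_population(96, rho_x = 0.9, rho_y = 0.9, lat_scale = 1,
                           seed = 40)
  ds <- generate_unimanual_dataset(pop, n_per_hand = 60, seed = 41)
  ds$rates <- add_noise_and_clip(ds$rates, noise_model(4), seed = 42)
  ds <- zscore_session(remove_block_means(ds))
  lb <- ds$labels
  Y <- as.matrix(lb[, c("v_rx", "v_ry", "v_lx", "v_ly")])
  ridge_r <- function(s) {
    m <- train_ridge(s$rates, Y, groups = lb$context, k = 3, seed = 43)
    mean(m$cv_r)
  }
  r_before <- ridge_r(ds)
  r_after <- ridge_r(remove_laterality(ds))
  expect_lt(abs(r_before - r_after), 0.02)
})
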