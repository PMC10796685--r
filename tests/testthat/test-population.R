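test_that("enforced tuning correlations are realized", {
  # exact mode: sample correlation equals rho to machine precision
  pop <- sample_population(192, rho_x = 0.3, rho_y = -0.6, seed = 1)
  expect_equal(cor(pop$tuning_uni[, "rx"], pop$tuning_uni[, "lx"]), 0.3,
               tolerance = 1e-10)
  expect_equal(cor(pop$tuning_uni[, "ry"], pop$tuning_uni[, "ly"]), -0.6,
               tolerance = 1e-10)
  # perfect correlation: left columns exactly parallel to right columns
  pop1 <- sample_population(64, rho_x = 1, rho_y = 1,
                            magnitudes = rep(8, 4), seed = 2)
  expect_equal(cor(pop1$tuning_uni[, "rx"], pop1$tuning_uni[, "lx"]), 1,
               tolerance = 1e-9)
  # mix mode: mean realized correlation over seeds is centered on rho
  mean_corr <- mean(vapply(1:100, function(s) {
    p <- sample_population(192, rho_x = 0, rho_y = 0, corr_mode = "mix", seed = s)
    cor(p$tuning_uni[, "rx"], p$tuning_uni[, "lx"])
  }, numeric(1)))
  expect_lt(abs(mean_corr), 0.03)
})

test_that("column norms, laterality scale and bimanual suppression are programmed", {
  mags <- c(10, 9, 6, 5)
  pop <- sample_population(128, lat_scale = 0.5, magnitudes = mags,
                           suppression = c(right = 0.9, left = 0.66), seed = 3)
  expect_equal(unname(sqrt(colSums(pop$tuning_uni^2))), mags, tolerance = 1e-9)
  expect_equal(sqrt(sum(pop$laterality^2)), 0.5 * mean(mags), tolerance = 1e-9)
  # bimanual columns: norm suppressed, correlation with unimanual column enforced
  expect_equal(sqrt(sum(pop$tuning_bi[, "lx"]^2)) / sqrt(sum(pop$tuning_uni[, "lx"]^2)),
               0.66, tolerance = 1e-9)
  expect_equal(cor(pop$tuning_uni[, "lx"], pop$tuning_bi[, "lx"]), 0.45,
               tolerance = 1e-9)
  expect_equal(cor(pop$tuning_uni[, "rx"], pop$tuning_bi[, "rx"]), 0.85,
               tolerance = 1e-9)
  # lat_scale = 0 removes the laterality column entirely
  pop0 <- sample_population(32, lat_scale = 0, seed = 4)
  expect_identical(pop0$laterality, rep(0, 32))
})

test_that("invalid population parameters are rejected", {
  expect_error(sample_population(1), "n_channels")
  expect_error(sample_population(16, rho_x = 1.2), "rho_x")
  expect_error(sample_population(16, lat_scale = -1), "lat_scale")
  expect_error(sample_population(16, magnitudes = c(1, 2, 3, -1)), "magnitudes")
})

test_that("encoding follows the linear tuning model", {
  pop <- fix_pop()
  # all-zero velocity with no laterality: rate is the baseline
  pop0 <- sample_population(16, lat_scale = 0, seed = 5)
  fr0 <- data.frame(d_rx = 0, d_ry = 0, d_lx = 0, d_ly = 0,
                    context = "unimanual_right")
  expect_equal(drop(encode_rates(pop0, fr0)), pop0$baseline)
  # hand-computed single channel: b0 + b_rx * d_rx
  fr <- data.frame(d_rx = 0.5, d_ry = 0, d_lx = 0, d_ly = 0,
                   context = "unimanual_right")
  r <- encode_rates(pop, fr)
  expect_equal(r[1, ], pop$baseline + 0.5 * pop$tuning_uni[, "rx"] +
                 pop$laterality)
  # flipping unimanual right -> left with d fixed changes rates by -2 b_lat
  # plus the hand-column difference; with d = 0 the difference is exactly
  # -2 b_lat
  frR <- data.frame(d_rx = 0, d_ry = 0, d_lx = 0, d_ly = 0,
                    context = "unimanual_right")
  frL <- transform(frR, context = "unimanual_left")
  expect_equal(drop(encode_rates(pop, frL) - encode_rates(pop, frR)),
               -2 * pop$laterality)
  # linearity in d within a context
  fr2 <- transform(fr, d_rx = 1.0)
  base <- encode_rates(pop, frR)
  expect_equal(2 * (encode_rates(pop, fr) - base),
               encode_rates(pop, fr2) - base, tolerance = 1e-12)
})

test_that("laterality code conventions", {
  expect_equal(laterality_code(c("unimanual_right", "unimanual_left",
                                 "bimanual", "no_movement")),
               c(1, -1, 1, 0))
  expect_equal(laterality_code("bimanual", bimanual = 0), 0)
})

test_that("noise addition is calibrated and clipping is total", {
  rates <- matrix(50, 200, 50)
  nm <- noise_model(3)
  noisy <- add_noise_and_clip(rates, nm, seed = 6)
  expect_equal(sd(noisy - rates), 3, tolerance = 0.05)  # 1e4 samples, ~5%
  expect_identical(add_noise_and_clip(rates, noise_model(0), seed = 6), rates)
  low <- matrix(0.5, 100, 100)
  clipped <- add_noise_and_clip(low, noise_model(5), seed = 7)
  expect_gte(min(clipped), 0)
  # sigma = 0 on negative input clips at zero
  expect_equal(add_noise_and_clip(matrix(-2, 2, 2), noise_model(0), seed = 1),
               matrix(0, 2, 2))
  # reproducible given seed
  expect_identical(add_noise_and_clip(rates, nm, seed = 8),
                   add_noise_and_clip(rates, nm, seed = 8))
})
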