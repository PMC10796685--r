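test_that("every bin of the stream gets exactly one condition label", {
  stream <- fix_stream()
  expect_false(any(stream$condition == ""))
  expect_equal(length(stream$condition), nrow(stream$inputs))
  # delay bins carry the upcoming trial's delay subtype; idle bins are rest
  sess <- generate_delayed_session(fix_pop(), n_per_type = 8, seed = 120)
  st <- label_stream(sess)
  delay <- sess$labels$epoch == "delay"
  type <- sess$trial_table$type[sess$labels$trial]
  expect_true(all(st$condition[delay] == paste0(type[delay], "_delay")))
  expect_true(all(st$condition[sess$labels$epoch == "idle"] == "rest"))
  # bimanual delay subtype present for bimanual trials
  expect_true("bimanual_delay" %in% st$condition)
})

test_that("clip resampling follows the dilation arithmetic", {
  x <- matrix(seq_len(60), 60, 2)
  # d_f = 0.5 compresses a length-60 clip to length 30
  expect_equal(resample_clip(x, d_f = 0.5)$length, 30L)
  # d_f = 1 is the identity
  expect_equal(resample_clip(x, d_f = 1)$inputs, x)
  # a linear ramp stays a linear ramp with preserved endpoints under dilation
  ramp <- matrix(seq(0, 1, length.out = 40), ncol = 1)
  out <- resample_clip(ramp, d_f = 2)$inputs
  expect_equal(out[1], 0); expect_equal(out[nrow(out)], 1)
  expect_equal(out, matrix(seq(0, 1, length.out = 80), ncol = 1),
               tolerance = 1e-12)
  # categorical labels resample by nearest neighbour, never interpolate
  cats <- rep(c(1L, 2L), each = 30)
  rc <- resample_clip(x, d_f = 2, categorical = cats)
  expect_true(all(rc$categorical %in% c(1L, 2L)))
  expect_equal(rc$categorical[1], 1L)
  expect_equal(rc$categorical[length(rc$categorical)], 2L)
  expect_error(resample_clip(x, d_f = 0.4), "d_f")
  expect_error(resample_clip(x[1:2, ], d_f = 0.5), "length")
})

test_that("train/validation pools are disjoint at trial level", {
  stream <- fix_stream()
  pools <- split_pools(stream, 0.1, seed = 121)
  expect_length(intersect(unique(pools$train$trial),
                          unique(pools$validation$trial)), 0)
  n_val <- length(unique(pools$validation$trial))
  n_tot <- length(unique(stream$trial))
  expect_lte(abs(n_val - 0.1 * n_tot), 1)
  # different seeds give different splits of the same size
  pools2 <- split_pools(stream, 0.1, seed = 122)
  expect_equal(length(unique(pools2$validation$trial)), n_val)
  expect_false(setequal(unique(pools$validation$trial),
                        unique(pools2$validation$trial)))
})

test_that("assembled snippets have exact shapes, balance and provenance", {
  stream <- fix_stream()
  sn <- assemble_snippets(stream, n_snippets = 10, snippet_len = 250,
                          seed = 123)
  expect_equal(dim(sn$inputs), c(10, 250, ncol(stream$inputs)))
  expect_equal(dim(sn$vel), c(10, 250, 4))
  expect_equal(dim(sn$ctx), c(10L, 250L))
  # provenance clip lengths tile each snippet exactly
  for (s in 1:10) expect_equal(sum(sn$provenance[[s]]$used), 250)
  # balance audit: every condition within +/- tolerance of its target share
  share <- sn$balance$counts / sum(sn$balance$counts)
  tgt <- sn$balance$targets[names(share)]
  expect_true(all(share - tgt <= 0.1 + 1e-9))
  expect_true(all(tgt - share <= 0.1 + 1e-9))
  # raw clip durations obey the [0.2, 0.8] x snippet-length bound
  lens <- unlist(lapply(sn$provenance, `[[`, "raw_len"))
  expect_true(all(lens >= 0.2 * 250 - 1 & lens <= 0.8 * 250 + 1))
  # dilation factors stay inside [0.5, 2]
  dfs <- unlist(lapply(sn$provenance, `[[`, "d_f"))
  expect_true(all(dfs >= 0.5 & dfs <= 2))
})

test_that("provenance replay reproduces snippets bit-exactly", {
  stream <- fix_stream()
  sn <- assemble_snippets(stream, n_snippets = 4, snippet_len = 200,
                          seed = 124)
  for (s in c(1, 4)) {
    rp <- replay_snippet(sn, stream, s)
    expect_identical(rp$inputs, sn$inputs[s, , ])
    expect_identical(rp$vel, sn$vel[s, , ])
    expect_identical(rp$ctx, unname(sn$ctx[s, ]))
  }
})

test_that("dilation factors are uniform on [0.5, 2]", {
  stream <- fix_stream()
  sn <- assemble_snippets(stream, n_snippets = 40, snippet_len = 250,
                          seed = 125)
  dfs <- unlist(lapply(sn$provenance, `[[`, "d_f"))
  # accepted clips' d_f should not be distinguishable from uniform
  ks <- suppressWarnings(ks.test(dfs, "punif", 0.5, 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("augmentation multiplies the available training duration", {
  stream <- fix_stream()
  sn <- assemble_snippets(stream, n_snippets = 60, snippet_len = 250,
                          seed = 126)
  total_snippet_bins <- 60 * 250
  expect_gt(total_snippet_bins / nrow(stream$inputs), 2)
  # at the full-scale settings (2000 x 10 s from ~25 min) the ratio
  # is 2000*500 / 75000 > 13; here we just check the mechanism scales
  expect_gt(2000 * 500 / (25 * 60 / 0.02), 10)
})

test_that("stereotyped snippets preserve task order", {
  stream <- fix_stream()
  sn <- stereotyped_snippets(stream, snippet_len = 100)
  expect_equal(sn$inputs[1, , ], stream$inputs[1:100, ])
  expect_equal(sn$inputs[2, , ], stream$inputs[101:200, ])
})
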