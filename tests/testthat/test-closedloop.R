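mk_state <- function(type = "unimanual_right", seed = 1,
                     config = task_config()) {
  bimanbci:::new_trial_state(type, config, seed)
}

test_that("assistance algebra matches its definition", {
  cfg <- task_config()
  st <- mk_state()
  u <- bimanbci:::unit_vec(st$target$right - st$pos$right)
  v <- c(0.3, 0.9)
  # full error assistance removes the orthogonal component exactly
  st1 <- task_step(st, c(v, 0, 0), assist_config(error_assist = 1), cfg)
  moved <- (st1$pos$right - st$pos$right) / cfg$dt
  expect_equal(unname(moved - sum(moved * u) * u), c(0, 0), tolerance = 1e-12)
  expect_equal(sum(moved * u), sum(v * u), tolerance = 1e-12)
  # no assistance: raw integration
  st2 <- task_step(st, c(v, 0, 0), assist_config(), cfg)
  expect_equal(st2$pos$right, st$pos$right + v * cfg$dt)
  # push assistance adds a vector of magnitude push * speed toward the target
  st3 <- task_step(st, c(v, 0, 0), assist_config(push_assist = 1), cfg)
  moved3 <- (st3$pos$right - st$pos$right) / cfg$dt
  expect_equal(unname(moved3), unname(v + sqrt(sum(v^2)) * u), tolerance = 1e-12)
  # error assistance is monotone in the orthogonal magnitude
  orth <- sapply(c(0, 0.3, 0.7, 1), function(ea) {
    s <- task_step(st, c(v, 0, 0), assist_config(error_assist = ea), cfg)
    m <- (s$pos$right - st$pos$right) / cfg$dt
    sqrt(sum((m - sum(m * u) * u)^2))
  })
  expect_true(all(diff(orth) <= 1e-12))
  # lock mode freezes the non-active cursor
  st4 <- task_step(st, c(v, 0.5, 0.5), assist_config(lock_mode = TRUE), cfg)
  expect_equal(st4$pos$left, st$pos$left)
})

test_that("oracle decoder acquires everything; zero decoder times out", {
  pop <- fix_pop()
  user <- sim_user(pop)
  res <- run_trials(oracle_decoder(), user, noise = NULL, n_trials = 8,
                    types = c("unimanual_right", "unimanual_left", "bimanual"),
                    seed = 131)
  expect_true(all(res$trials$success))
  expect_true(all(res$trials$tta < 5))
  res0 <- run_trials(zero_decoder(), user, noise = NULL, n_trials = 4,
                     seed = 132)
  expect_true(all(!res0$trials$success))
  expect_true(all(res0$trials$tta == 10))
})

test_that("dwell logic agrees with a brute-force trace checker", {
  # brute force: success at the first bin where both cursors have been
  # simultaneously inside their targets for >= dwell seconds without a break
  cfg <- task_config(timeout = 2)
  set.seed(133)
  for (rep in 1:300) {
    n <- 100
    inside_r <- runif(n) < 0.8
    inside_l <- runif(n) < 0.8
    both <- inside_r & inside_l
    # oracle: running length of consecutive `both`
    runlen <- Reduce(function(a, b) ifelse(b, a + 1, 0), both, accumulate = TRUE)
    need <- cfg$dwell / cfg$dt
    first <- which(runlen >= need)[1]
    # drive the task state with velocities teleporting cursors in/out
    st <- mk_state("bimanual", seed = rep, config = cfg)
    got <- NA
    for (t in seq_len(n)) {
      # place cursors exactly on/off their targets before stepping
      st$pos$right <- st$target$right + if (inside_r[t]) c(0, 0) else c(1, 0)
      st$pos$left <- st$target$left + if (inside_l[t]) c(0, 0) else c(1, 0)
      st <- task_step(st, c(0, 0, 0, 0), assist_config(), cfg)
      if (st$done && st$success) { got <- t; break }
      if (st$done) break
    }
    expect_identical(got, if (is.na(first) || first > cfg$timeout / cfg$dt)
      NA else first)
    if (rep %% 100 == 0 && !is.na(got)) {
      expect_true(all(both[(got - need + 1):got]))
    }
  }
})

test_that("the simulated user points at targets and respects strategy", {
  pop <- fix_pop()
  cfg <- task_config()
  user <- sim_user(pop, reaction_time = 0.2)
  st <- mk_state("bimanual", seed = 134)
  st$t <- 0.5  # past the reaction time
  us <- user_step(user, st, noise = NULL, seed = 1, config = cfg)
  expect_equal(sqrt(sum(us$intention[1:2]^2)), 1, tolerance = 1e-9)
  expect_equal(us$context, "bimanual")
  # intention is zero inside the target
  st2 <- st; st2$pos$right <- st2$target$right
  us2 <- user_step(user, st2, noise = NULL, seed = 1, config = cfg)
  expect_equal(us2$intention[1:2], c(0, 0))
  expect_equal(us2$context, "unimanual_left")
  # zero intention within the reaction time
  st3 <- st; st3$t <- 0.1
  us3 <- user_step(user, st3, noise = NULL, seed = 1, config = cfg)
  expect_equal(us3$intention, c(0, 0, 0, 0))
  # sequential strategy: at most one hand active per bin
  seq_user <- sim_user(pop, strategy = "sequential")
  mem <- list()
  for (i in 1:10) {
    us4 <- user_step(seq_user, st, noise = NULL, seed = i, mem = mem,
                     config = cfg)
    mem <- us4$mem
    expect_lte(sum(us4$intention[1:2] != 0) > 0, 1)
    active_hands <- (any(us4$intention[1:2] != 0)) + (any(us4$intention[3:4] != 0))
    expect_lte(active_hands, 1)
  }
  # the emitted bin equals the noiseless encoding in expectation
  nm <- noise_model(2)
  draws <- vapply(1:2000, function(i)
    user_step(user, st, noise = nm, seed = i, config = cfg)$rates,
    numeric(pop$n_channels))
  noiseless <- user_step(user, st, noise = NULL, seed = 1, config = cfg)$rates
  se <- 2 / sqrt(2000)
  expect_lt(max(abs(rowMeans(draws) - noiseless)) , 6 * se + 0.05)
})

test_that("angular error and jitter metrics match hand-computed cases", {
  # decoded along / orthogonal / opposite to the target direction
  log <- cbind(t = c(0.35, 0.4), prx = 0, pry = 0, plx = 0, ply = 0,
               trx = 1, try = 0, tlx = 0, tly = 0,
               vrx = c(1, 1), vry = 0, vlx = 0, vly = 0)
  expect_equal(bimanbci:::angular_errors(log, "unimanual_right")[["right"]], 0)
  log2 <- log; log2[, "vrx"] <- 0; log2[, "vry"] <- 1
  expect_equal(bimanbci:::angular_errors(log2, "unimanual_right")[["right"]], 90)
  log3 <- log; log3[, "vrx"] <- -1
  expect_equal(bimanbci:::angular_errors(log3, "unimanual_right")[["right"]], 180)
  # jitter: rest speed over move speed
  vel <- rbind(matrix(rep(c(2, 0, 1, 0), 10), 10, 4, byrow = TRUE),
               matrix(rep(c(1, 0, 2, 0), 10), 10, 4, byrow = TRUE))
  active <- rep(c("right", "left"), each = 10)
  j <- cursor_jitter(vel, active)
  expect_equal(unname(j), c(0.5, 0.5))
  expect_equal(unname(cursor_jitter(vel * c(rep(1, 10), rep(0, 10)), active)[["right"]]), 0)
  expect_error(cursor_jitter(vel, rep("right", 20)), "movement bins")
})

test_that("closed-loop rollouts are reproducible given the seed", {
  pop <- fix_pop()
  user <- sim_user(pop)
  r1 <- run_trials(oracle_decoder(), user, noise = noise_model(2),
                   n_trials = 3, seed = 135)
  r2 <- run_trials(oracle_decoder(), user, noise = noise_model(2),
                   n_trials = 3, seed = 135)
  expect_identical(r1$trials, r2$trials)
})
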