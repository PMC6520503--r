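test_that("block schedules reproduce the three experiments' trial counts", {
  # Experiment 1: 102 = 18 context + 36 unperturbed (6 channel) + 48 jump
  # (12 channel), for both reward assignments
  for (i in 1:2) {
    cond <- exp1_conditions()[i, ]
    s <- build_block_schedule(1, cond, seed = 42)
    expect_equal(nrow(s), 102)
    expect_equal(sum(s$phase == "context"), 18)
    main <- s[s$phase == "main", ]
    up <- main[main$jump_direction == "none", ]
    expect_equal(nrow(up), 36)
    expect_equal(sum(up$trial_type == "channel"), 6)
    expect_equal(as.integer(table(up$cued_target)[c("left", "center", "right")]),
                 c(12L, 12L, 12L))
    jump <- main[main$jump_direction != "none", ]
    expect_equal(nrow(jump), 48)
    expect_equal(sum(jump$trial_type == "channel"), 12)
    for (d in c("left", "right")) {
      jd <- jump[jump$jump_direction == d, ]
      expect_equal(nrow(jd), 24)
      expect_equal(sum(jd$cued_target == "center"), 12)
      expect_equal(sum(jd$cued_target == d), 12)
    }
  }

  # Experiment 2: 12 context + 100 (center probable) or 110 (outer
  # probable) remaining; half of center-target trials are channel trials
  s_out <- build_block_schedule(2, exp2_conditions()[1, ], seed = 1)
  s_cen <- build_block_schedule(2, exp2_conditions()[2, ], seed = 1)
  expect_equal(nrow(s_out), 122)
  expect_equal(nrow(s_cen), 112)
  expect_equal(sum(s_out$phase == "main"), 110)
  expect_equal(sum(s_cen$phase == "main"), 100)
  for (s in list(s_out, s_cen)) {
    expect_equal(sum(s$phase == "context"), 12)
    main <- s[s$phase == "main", ]
    expect_equal(sum(main$jump_direction != "none"), 60)
    cen <- main[main$cued_target == "center", ]
    expect_equal(sum(cen$trial_type == "channel"), nrow(cen) / 2)
  }
  up_out <- s_out[s_out$phase == "main" & s_out$jump_direction == "none", ]
  expect_equal(as.integer(table(up_out$cued_target)[c("left", "center", "right")]),
               c(20L, 10L, 20L))

  # Experiment 3: 18 context + 118 main (108 jump of which 36 channel,
  # 10 unperturbed of which 5 channel), for every grid condition
  for (i in seq_len(nrow(exp3_conditions()))) {
    cond <- exp3_conditions()[i, ]
    s <- build_block_schedule(3, cond, seed = i)
    expect_equal(nrow(s), 136)
    expect_equal(sum(s$phase == "context"), 18)
    main <- s[s$phase == "main", ]
    expect_equal(nrow(main), 118)
    jump <- main[main$jump_direction != "none", ]
    expect_equal(nrow(jump), 108)
    expect_equal(sum(jump$trial_type == "channel"), 36)
    up <- main[main$jump_direction == "none", ]
    expect_equal(nrow(up), 10)
    expect_equal(sum(up$trial_type == "channel"), 5)
    # cued-target proportions follow the block's P_O : P_C ratio
    for (d in c("left", "right")) {
      jd <- jump[jump$jump_direction == d, ]
      expect_equal(sum(jd$cued_target == d) / sum(jd$cued_target == "center"),
                   cond$p_ratio)
    }
  }
})

test_that("schedules put context trials first and shuffle reproducibly", {
  cond <- exp3_conditions()[3, ]
  a <- build_block_schedule(3, cond, seed = 7)
  b <- build_block_schedule(3, cond, seed = 7)
  c <- build_block_schedule(3, cond, seed = 8)
  expect_identical(a, b)
  expect_true(all(a$phase[1:18] == "context"))
  expect_false(identical(a$cued_target, c$cued_target))
  # a different seed changes only the order, never the counts
  expect_equal(table(paste(a$trial_type, a$jump_direction, a$cued_target)),
               table(paste(c$trial_type, c$jump_direction, c$cued_target)))
  expect_error(build_block_schedule(4, cond), "unknown experiment")
  bad <- cond; bad$p_outer <- 0.55; bad$p_center <- 0.45
  expect_error(build_block_schedule(3, bad), "design grid")
})

test_that("the value grid has 8 conditions spanning 5 relative values", {
  g <- exp3_conditions()
  expect_equal(nrow(g), 8)
  expect_equal(sort(unique(g$rel_value)), c(0.25, 0.5, 1, 2, 4))
  expect_true(all(abs(g$p_outer + g$p_center - 1) < 1e-12))
})

test_that("subject parameter sampling is seeded and respects its bounds", {
  m <- list(intercept = 1.5, slope = -0.8, risk_weight = 0.68, noise_sd = 0.5)
  s0 <- list(intercept = 0, slope = 0, risk_weight = 0, noise_sd = 0)
  deg <- sample_subject_params(m, s0, n_subjects = 5, seed = 1)
  expect_true(all(deg$intercept == 1.5 & deg$slope == -0.8 &
                    deg$risk_weight == 0.68))

  s <- list(intercept = 0.5, slope = 0.3, risk_weight = 0.1, noise_sd = 0)
  a <- sample_subject_params(m, s, n_subjects = 12, seed = 99)
  b <- sample_subject_params(m, s, n_subjects = 12, seed = 99)
  expect_identical(a, b)
  expect_equal(nrow(a), 12)
  expect_true(all(a$risk_weight >= 0 & a$risk_weight <= 1))
  expect_error(sample_subject_params(m, lapply(s, function(x) -1), 3),
               "non-negative")
})

test_that("truncated risk-weight draws match the quadrature mean", {
  m <- list(intercept = 0, slope = 0, risk_weight = 0.68, noise_sd = 1)
  s <- list(intercept = 0, slope = 0, risk_weight = 0.1, noise_sd = 0)
  draws <- sample_subject_params(m, s, n_subjects = 1e5, seed = 4)$risk_weight
  expect_lt(abs(mean(draws) - truncnorm_mean_quadrature(0.68, 0.1)), 0.01)
})

test_that("expected gains follow the generating linear model", {
  prm <- list(intercept = 1.1, slope = -0.7, risk_weight = 0.68)
  flat <- condition_design(3, 10, 10, 0.5, 0.5, c(0, 1, 0))
  for (mod in c("probability", "reward", "value_neutral", "value_risk"))
    expect_equal(expected_gain(prm, flat, mod), 1.1)

  # w = 0.5 reduces the risk-sensitive gain to the risk-neutral one
  prm$risk_weight <- 0.5
  for (i in seq_len(nrow(exp3_conditions()))) {
    cond <- exp3_conditions()[i, ]
    expect_equal(expected_gain(prm, cond, "value_risk"),
                 expected_gain(prm, cond, "value_neutral"))
  }

  prm <- list(intercept = 0, slope = 1, risk_weight = 1)
  cond <- condition_design(3, 20, 10, 1 / 3, 2 / 3, c(0, 1, 0))  # r=2, p=0.5
  expect_equal(expected_gain(prm, cond, "value_risk"), 2 * log(0.5),
               tolerance = 1e-10)
})

test_that("gain tables have the right size, noise scale and zero-noise limit", {
  conds <- exp3_conditions()
  subj <- sample_subject_params(n_subjects = 10, seed = 2)
  g <- simulate_gain_table(conds, subj, trials_per_cell = 18, seed = 3)
  expect_equal(nrow(g), 8 * 10 * 2)

  subj0 <- subj; subj0$noise_sd <- 1e-12
  g0 <- simulate_gain_table(conds, subj0, trials_per_cell = 18, seed = 3)
  mu <- mapply(function(si, ci) expected_gain(subj0[si, ], conds[ci, ]),
               match(g0$subject_id, subj0$subject_id),
               match(g0$condition, conds$label))
  expect_equal(g0$gain, unname(mu), tolerance = 1e-9)

  # sampling variance of one cell matches noise_sd^2 / trials_per_cell
  one <- data.frame(subject_id = sprintf("s%04d", 1:5000), intercept = 1,
                    slope = -0.8, risk_weight = 0.5, noise_sd = 0.5)
  gv <- simulate_gain_table(conds[1, ], one, trials_per_cell = 18, seed = 5,
                            directions = "left")
  expect_lt(abs(var(gv$gain) / (0.5^2 / 18) - 1), 0.05)
  expect_error(simulate_gain_table(conds[0, ], subj), "empty")
})

test_that("synthesized traces hit the window mean exactly and average out noise", {
  z <- synthesize_trace(0, noise_sd = 0)
  expect_true(all(z$value == 0))

  tr <- synthesize_trace(1, onset = 125, rise_time = 60, noise_sd = 0)
  expect_lt(abs(response_gain(tr$value, tr$t_ms) - 1), 1e-9)
  expect_true(all(tr$value[tr$t_ms < 125] == 0))

  set.seed(8)
  m <- rowMeans(vapply(1:500, function(i)
    synthesize_trace(1, noise_sd = 0.5)$value, numeric(501)))
  tt <- synthesize_trace(1, noise_sd = 0)$t_ms
  expect_lt(abs(response_gain(m, tt) - 1), 0.05)

  expect_error(synthesize_trace(1, rise_time = 0), "rise_time")
  expect_error(synthesize_trace(1, onset = 500, duration = 400), "onset")
})

test_that("hit simulation follows its logistic link", {
  set.seed(3)
  h0 <- simulate_hits(rnorm(1e4), a = 0.6, b = 0)
  expect_lt(abs(mean(h0) - plogis(0.6)), 3 * sqrt(0.25 / 1e4))

  for (g in c(-1, 0.5, 2)) {
    p <- plogis(0.2 + 0.8 * g)
    h <- simulate_hits(rep(g, 1e4), a = 0.2, b = 0.8)
    expect_lt(abs(mean(h) - p), 3 * sqrt(p * (1 - p) / 1e4))
  }

  # near-infinite slope thresholds on the gain
  expect_true(all(simulate_hits(c(0.1, 1), a = 0, b = 1e6)))
  expect_false(any(simulate_hits(c(-0.1, -1), a = 0, b = 1e6)))

  # calibrated default intercept reproduces the pooled hit-rate anchor
  gains <- reachgain:::default_corrective_gains()
  hp <- default_hit_params()
  expect_equal(mean(plogis(hp$a + hp$b * gains)), 0.738, tolerance = 1e-6)
})

test_that("generated gains recover the generating slope by regression", {
  m <- list(intercept = 1.5, slope = -0.8, risk_weight = 0.68, noise_sd = 0.5)
  s0 <- list(intercept = 0, slope = 0, risk_weight = 0, noise_sd = 0)
  subj <- sample_subject_params(m, s0, n_subjects = 12, seed = 6)
  g <- simulate_gain_table(exp3_conditions(), subj, trials_per_cell = 18,
                           seed = 7)
  x <- model_predictor(g, "value_risk", w = 0.68)
  fit <- summary(lm(g$gain ~ x))$coefficients
  expect_lt(abs(fit["x", "Estimate"] - (-0.8)) / fit["x", "Std. Error"], 3)
})
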