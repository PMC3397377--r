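test_that("memory update follows the exponential filter", {
  expect_equal(update_memory(0.5, "R", 0.686), 0.686 * 0.5 + 0.314)
  expect_equal(update_memory(1.0, "R", 0.3), 1.0)   # fixed point
  expect_equal(update_memory(0.0, "A", 0.3), 0.0)   # fixed point

  # four consecutive alternations from M = 1 at delta = 0.5: 0.5^4
  m <- 1
  for (i in 1:4) m <- update_memory(m, "A", 0.5)
  expect_equal(m, 0.0625)

  # stays in [0, 1] under arbitrary update streams
  set.seed(8)
  m <- 0.5
  for (i in 1:200) {
    m <- update_memory(m, sample(c("R", "A"), 1), runif(1, 0.05, 0.95))
    expect_gte(m, 0); expect_lte(m, 1)
  }
})

test_that("initial condition is signed by transition and bounded", {
  expect_equal(initial_condition(0.5, "R", k = 0.1, x_offset = 0), 0)
  expect_equal(initial_condition(0.75, "R", k = 0.1181, x_offset = 0.0034),
               0.1181 * 0.25 + 0.0034)
  expect_equal(initial_condition(0.75, "A", k = 0.1181, x_offset = 0.0034),
               -(0.1181 * 0.25 + 0.0034))
  # |x0| never exceeds k/2 + x_offset
  for (m in seq(0, 1, by = 0.1))
    expect_lte(abs(initial_condition(m, "R", 0.2, 0.01)), 0.2 / 2 + 0.01)
})

test_that("threshold update moves by z_down/z_up and clamps to its range", {
  pars <- exp2_pars  # z_down 0.0034, z_up 0.1635, z_max 0.2062
  expect_equal(update_threshold(0.2062, FALSE, pars), 0.2062)  # upper clamp
  expect_equal(update_threshold(0.2062, TRUE, pars), 0.2028)
  lo <- pars$k / 2 + pars$x_offset
  expect_equal(update_threshold(lo, TRUE, pars), lo)           # lower clamp

  # bounds hold after any update stream
  set.seed(13)
  z <- pars$z_max
  for (i in 1:500) {
    z <- update_threshold(z, runif(1) < 0.8, pars)
    expect_gte(z, lo); expect_lte(z, pars$z_max)
  }
})

test_that("simulate_trial is deterministic given seed and Bernoulli-consistent", {
  st <- model_state(exp2_pars)
  set.seed(5); a <- simulate_trial(st, "R", 1L, exp2_pars)
  set.seed(5); b <- simulate_trial(st, "R", 1L, exp2_pars)
  expect_identical(a, b)

  # empirical error fraction matches the closed-form ER of the trial state
  st3 <- model_state(exp2_pars, memory = 0.8, z_current = 0.15,
                     trial_index = 5L)
  set.seed(6)
  outs <- replicate(1e4, simulate_trial(st3, "A", 2L, exp2_pars)$trial$correct)
  er_th <- seqddm:::.er_closed_cpp(
    0.15, initial_condition(0.8, "A", exp2_pars$k, exp2_pars$x_offset),
    exp2_pars$mu_tilde)
  expect_lt(abs(mean(!outs) - er_th), 3 * sqrt(er_th * (1 - er_th) / 1e4))
})

test_that("degenerate adaptation parameters reduce to the pure DDM", {
  # k, x_offset, z_down, z_up shrunk to (near) zero: every trial identical
  pars0 <- adaptive_params(mu_tilde = 19.3312, t_nd = 0.3359, k = 1e-12,
                           x_offset = 1e-12, delta = 0.5, z_down = 1e-15,
                           z_up = 1e-15, z_max = 0.2)
  stim <- data.frame(block = 1L, trial = 1:400, p_alt = 0.5,
                     stimulus = generate_markov_stimuli(400, 0.5, seed = 2))
  sim <- simulate_session(stim, pars0, seed = 3)
  p_pure <- ddm_params(19.3312, 0.2, 0)
  expect_equal(sim$er_trial, rep(error_rate(p_pure), 400), tolerance = 1e-6)
  rt_th <- 0.3359 + mean_decision_time(p_pure)
  expect_equal(sim$rt, rep(rt_th, 400), tolerance = 1e-6)
  # empirical error fraction consistent with the pure-DDM ER
  er <- error_rate(p_pure)
  expect_lt(abs(mean(!sim$correct) - er), 3 * sqrt(er * (1 - er) / 400))
})

test_that("compiled session kernel matches the R reference implementation", {
  stim <- generate_markov_stimuli(60, 0.5, seed = 21)
  set.seed(77)
  cpp <- seqddm:::.simulate_block_cpp(stim, exp2_pars$mu_tilde,
    exp2_pars$t_nd, exp2_pars$k, exp2_pars$x_offset, exp2_pars$delta,
    exp2_pars$z_down, exp2_pars$z_up, exp2_pars$z_max)
  set.seed(77)
  ref <- seqddm:::.simulate_block_r(stim, exp2_pars)
  expect_equal(cpp$correct, ref$correct)
  expect_equal(cpp$rt, ref$rt, tolerance = 1e-12)
  expect_equal(cpp$x0_tilde, ref$x0_tilde, tolerance = 1e-12)
  expect_equal(cpp$z_tilde, ref$z_tilde, tolerance = 1e-12)
  expect_equal(cpp$transition, ref$transition)
})

test_that("session simulation re-initializes state per block and pass", {
  stim <- data.frame(block = rep(1:2, each = 50),
                     trial = rep(1:50, 2), p_alt = 0.5,
                     stimulus = c(generate_markov_stimuli(50, 0.5, seed = 31),
                                  generate_markov_stimuli(50, 0.5, seed = 32)))
  sim <- simulate_session(stim, exp2_pars, n_passes = 5, seed = 41)
  expect_equal(nrow(sim), 500)  # 2 blocks x 50 trials x 5 passes
  firsts <- sim[sim$trial == 1, ]
  expect_true(all(firsts$z_tilde == exp2_pars$z_max))
  expect_true(all(firsts$x0_tilde == 0))
  expect_true(all(is.na(firsts$transition)))

  # determinism and pass-stability of child streams
  sim2 <- simulate_session(stim, exp2_pars, n_passes = 5, seed = 41)
  expect_identical(sim, sim2)
  sim1 <- simulate_session(stim, exp2_pars, n_passes = 1, seed = 41)
  expect_equal(sim[sim$pass == 1, ], sim1, ignore_attr = TRUE)

  expect_error(simulate_session(data.frame(), exp2_pars), "non-empty")
})

test_that("memory priming is symmetric under relabelling repetitions and alternations", {
  # mirroring the stimulus sequence swaps every R transition for an A; the
  # memory term of the priming is antisymmetric in both sign and memory
  # deviation, so with the same RNG stream and no fixed offset the joint
  # (correctness, RT) sequence is unchanged
  stim <- generate_markov_stimuli(300, 0.3, seed = 51)
  mirrored <- stim
  flip <- cumsum(c(FALSE, stim[-1] == stim[-300])) %% 2 == 1
  mirrored[-1] <- ifelse(flip[-1], 3L - stim[1], stim[1])
  # mirrored has transition R exactly where stim has A
  t1 <- c(NA, stim[-1] == stim[-300])
  t2 <- c(NA, mirrored[-1] == mirrored[-300])
  expect_true(all(t1[-1] != t2[-1]))

  pars <- adaptive_params(exp2_pars$mu_tilde, exp2_pars$t_nd, exp2_pars$k,
                          x_offset = 1e-12, delta = exp2_pars$delta,
                          z_down = exp2_pars$z_down, z_up = exp2_pars$z_up,
                          z_max = exp2_pars$z_max)
  set.seed(61)
  a <- seqddm:::.simulate_block_r(stim, pars)
  set.seed(61)
  b <- seqddm:::.simulate_block_r(mirrored, pars)
  expect_equal(a$correct, b$correct)
  expect_equal(a$rt, b$rt, tolerance = 1e-9)
  expect_equal(a$x0_tilde, b$x0_tilde, tolerance = 1e-9)
})

test_that("long repetition runs speed up repetition responses", {
  stim <- data.frame(block = 1L, trial = 1:100, p_alt = 0,
                     stimulus = rep(1L, 100))
  sim <- simulate_session(stim, exp1_pars, seed = 71)
  expect_gt(sim$memory[90], 0.95)  # memory saturates toward 1
  late <- sim$rt[85:100][sim$correct[85:100]]
  expect_lt(mean(late), sim$rt[3])
})

test_that("adaptive parameter validation enforces the threshold range", {
  expect_error(adaptive_params(10, 0.3, 0.5, 0.1, 0.5, 0.01, 0.1,
                               z_max = 0.2), "z_max")
  expect_error(adaptive_params(10, 0.3, 0.1, 0.01, 1.2, 0.01, 0.1, 0.3),
               "delta")
  expect_error(model_state(exp2_pars, memory = 1.5), "memory")
  expect_error(model_state(exp2_pars, z_current = 0.01), "range")
})
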