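test_that("go-stimulus posterior update follows Bayes' rule", {
  expect_equal(update_pd(0.5, 1, 0.7), 0.7)
  expect_equal(update_pd(0.5, 0, 0.7), 0.3)
  # uninformative likelihood leaves the posterior unchanged
  expect_equal(update_pd(0.5, 1, 0.5), 0.5)
  expect_equal(update_pd(0.31, 0, 0.5), 0.31)
  # certainty is absorbing
  expect_equal(update_pd(1, 0, 0.9), 1)
  expect_equal(update_pd(0, 1, 0.9), 0)
  # vectorized over observations
  expect_equal(update_pd(c(0.5, 0.5), c(1, 0), 0.7), c(0.7, 0.3))
  expect_error(update_pd(1.2, 1, 0.7), "p_d")
  expect_error(update_pd(0.5, 2, 0.7), "binary")
  expect_error(update_pd(0.5, 1, 0.3), "q_d")
})

test_that("onset hazard matches the geometric-mixture formula", {
  expect_equal(hazard(5, 0, 0.2), 0)
  expect_equal(hazard(c(1, 7, 30), 1, 0.2), rep(0.2, 3))
  expect_equal(hazard(1, 0.25, 0.1), 0.025)
  # direct evaluation at a later step
  t <- 8; r <- 0.3; q <- 0.07
  expect_equal(hazard(t, r, q),
               r * q * (1 - q)^(t - 1) / (r * (1 - q)^(t - 1) + (1 - r)))
  expect_error(hazard(0, 0.25, 0.1), "t")
})

test_that("stop-onset posterior update handles evidence and absorption", {
  p <- task_params(r = 0.25, q = 0.1, q_s = 0.72)
  # frozen value from the exact one-step enumeration (0.018 / 0.291)
  expect_equal(update_pz(0, 1, 1, p), 0.0618556701, tolerance = 1e-9)
  # detected signal is absorbing
  expect_equal(update_pz(1, 0, 3, p), 1)
  expect_equal(update_pz(1, 1, 3, p), 1)
  # no stop trials: posterior pinned at zero
  p0 <- task_params(r = 0, q = 0.1, q_s = 0.72)
  expect_equal(update_pz(0, 1, 1, p0), 0)
  expect_equal(update_pz(0, 0, 5, p0), 0)
  expect_error(update_pz(-0.1, 1, 1, p), "p_z")
})

test_that("stop-trial posterior combines onset posterior and survival", {
  expect_equal(prob_stop_trial(0, 0, 0.25, 0.1), 0.25)
  expect_equal(prob_stop_trial(1, 17, 0.25, 0.1), 1)
  # decreasing in t while no signal is detected; frozen formula evaluation
  expect_equal(prob_stop_trial(0, 20, 0.25, 0.1), 0.0389472, tolerance = 1e-6)
  v <- prob_stop_trial(0, 0:30, 0.25, 0.1)
  expect_true(all(diff(v) < 0))
  # with uninformative stop evidence (q_s = 0.5) the recursion's derived
  # p_s stays at the prior r, matching the enumeration oracle: p_z rises
  # along the onset hazard while the survival term falls in step
  p <- task_params(r = 0.25, q = 0.1, q_s = 0.5)
  p_z <- 0
  for (t in 1:12) p_z <- update_pz(p_z, rbinom(1, 1, 0.5), t, p)
  orc <- posterior_oracle(rep(0, 12), rep(1, 12), p)
  expect_equal(unname(orc["p_s"]), 0.25, tolerance = 1e-12)
  expect_equal(prob_stop_trial(p_z, 12, 0.25, 0.1), 0.25, tolerance = 1e-12)
})

test_that("recursive posteriors match the brute-force enumeration oracle", {
  set.seed(101)
  for (rep in 1:5) {
    p <- random_params()
    for (i in 1:60) {
      T <- sample(1:8, 1)
      xs <- rbinom(T, 1, 0.5); ys <- rbinom(T, 1, 0.5)
      expect_equal(belief_trajectory_end(xs, ys, p),
                   posterior_oracle(xs, ys, p), tolerance = 1e-10)
    }
  }
  # closed-form product of likelihood ratios for a pure-evidence stream
  p9 <- task_params(q_d = 0.9)
  expected <- 0.9^5 * 0.5 / (0.9^5 * 0.5 + 0.1^5 * 0.5)
  expect_equal(unname(belief_trajectory_end(rep(1, 5), rep(0, 5), p9)["p_d"]),
               expected, tolerance = 1e-12)
  # no evidence returns the priors
  expect_equal(posterior_oracle(integer(0), integer(0), p9),
               c(p_d = 0.5, p_z = 0, p_s = 0.25))
  expect_error(posterior_oracle(rep(1, 20), rep(1, 20), p9), "too long")
})

test_that("posteriors stay in [0,1] and p_s dominates p_z on any stream", {
  set.seed(202)
  for (rep in 1:20) {
    p <- random_params()
    T <- 40
    xs <- rbinom(T, 1, runif(1)); ys <- rbinom(T, 1, runif(1))
    p_d <- p$p_d_prior; p_z <- 0
    for (t in seq_len(T)) {
      p_d <- update_pd(p_d, xs[t], p$q_d)
      p_z <- update_pz(p_z, ys[t], t, p)
      p_s <- prob_stop_trial(p_z, t, p$r, p$q)
      expect_true(p_d >= 0 && p_d <= 1)
      expect_true(p_z >= 0 && p_z <= 1)
      expect_true(p_s >= p_z - 1e-15 && p_s <= 1)
    }
  }
  # r = 0 forces p_s = p_z = 0 for all t
  p0 <- task_params(r = 0, q = 0.1)
  p_z <- 0
  for (t in 1:20) {
    p_z <- update_pz(p_z, rbinom(1, 1, 0.5), t, p0)
    expect_equal(p_z, 0)
    expect_equal(prob_stop_trial(p_z, t, 0, 0.1), 0)
  }
})

test_that("sampled onset steps follow the geometric prior", {
  set.seed(7)
  q <- 0.08
  th <- sample_theta(20000, q)
  se <- sd(th) / sqrt(length(th))
  expect_lt(abs(mean(th) - 1 / q), 3 * se)
  expect_true(all(th >= 1))
})

test_that("observation sampling respects the latent structure", {
  p <- task_params(q_s = 0.72, q_d = 0.8)
  set.seed(11)
  # go trial: y is pre-onset noise throughout
  obs <- sample_observations(trial_latents(d = 0, s = 0), p, horizon = 50)
  # repeat to get a tight Monte-Carlo estimate
  ys <- replicate(40, sample_observations(trial_latents(0, 0), p, 50)$y)
  m <- mean(ys); n <- length(ys)
  expect_lt(abs(m - (1 - p$q_s)), 3 * sqrt(0.28 * 0.72 / n))
  # deterministic go evidence
  p1 <- task_params(q_d = 1)
  obs1 <- sample_observations(trial_latents(1, 0), p1, horizon = 30)
  expect_true(all(obs1$x == 1))
  # y-distribution switches at the onset step
  set.seed(12)
  reps <- replicate(400, sample_observations(
    trial_latents(1, 1, theta = 3), p, horizon = 10)$y)
  pre <- mean(reps[1:2, ]); post <- mean(reps[3:10, ])
  expect_lt(abs(pre - 0.28), 3 * sqrt(0.28 * 0.72 / (2 * 400)))
  expect_lt(abs(post - 0.72), 3 * sqrt(0.28 * 0.72 / (8 * 400)))
  # a stop trial without an onset step violates the contract
  expect_error(trial_latents(1, 1), "theta")
  expect_error(trial_latents(1, 0, theta = 4), "absent")
})
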