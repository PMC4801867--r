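test_that("terminal value and Go Q-factor match their closed forms", {
  p <- ref_params()   # c = 0.002, c_s = 0.4, D = 50
  expect_equal(terminal_value(1, p), 0.1)
  expect_equal(terminal_value(0, task_params(c = 0, D = 10)), 1)
  expect_equal(terminal_value(0.25, p), 0.85)
  expect_equal(q_go(1, 0, 0, task_params(c = 0.002)), 0)
  # going on a certain stop trial costs c*t + c_s regardless of p_d
  expect_equal(q_go(c(0.2, 0.8), 1, 10, p), rep(0.002 * 10 + 0.4, 2))
  expect_equal(q_go(0.5, 0.25, 10, p), 0.495)
  expect_error(q_go(0.5, 0.25, 60, p), "t")
})

test_that("predictive observation distribution is a proper factorized law", {
  p <- ref_params()
  m <- predictive_obs_dist(0.37, 0.12, 9, p)
  expect_equal(sum(m), 1, tolerance = 1e-12)
  expect_true(all(m >= 0))
  # symmetric go evidence gives a flat x marginal
  m2 <- predictive_obs_dist(0.5, 0.3, 4, task_params(q_d = 0.5))
  expect_equal(unname(rowSums(m2)), c(0.5, 0.5))
  # certainty about d collapses the x mixture onto one likelihood
  m3 <- predictive_obs_dist(1, 0, 1, task_params(q_d = 0.7))
  expect_equal(unname(rowSums(m3)[2]), 0.7)
})

test_that("expected next value averages correctly over observations", {
  p <- ref_params()
  g <- belief_grid(5, 5)
  K <- matrix(3.14, 5, 5)
  expect_equal(expected_next_value(0.3, 0.2, 7, K, p, g), 3.14)
  # no information and no hazard: belief does not move, so the expectation
  # is the value at the current (on-grid) belief
  p0 <- task_params(r = 0, q = 0.1, q_d = 0.5, q_s = 0.5)
  V <- matrix(runif(25), 5, 5)
  expect_equal(expected_next_value(g$centers_d[2], g$centers_z[1], 3,
                                   V, p0, g),
               V[2, 1], tolerance = 1e-12)
  # independent enumeration over the four observation outcomes, mixing over
  # the latent state implied by the belief
  pd <- 0.42; pz <- 0.18; t <- 3
  h1 <- hazard(t + 1, p$r, p$q)
  pz1 <- pz + (1 - pz) * h1          # P(signal on at t+1 | belief)
  ev <- 0
  for (x in 0:1) for (y in 0:1) {
    px <- pd * (if (x == 1) p$q_d else 1 - p$q_d) +
      (1 - pd) * (if (x == 1) 1 - p$q_d else p$q_d)
    py <- pz1 * (if (y == 1) p$q_s else 1 - p$q_s) +
      (1 - pz1) * (if (y == 1) 1 - p$q_s else p$q_s)
    ndp <- update_pd(pd, x, p$q_d)
    nzp <- update_pz(pz, y, t + 1, p)
    wd <- stopsignal:::interp_weights(ndp, g$centers_d)
    wz <- stopsignal:::interp_weights(nzp, g$centers_z)
    ev <- ev + px * py * drop(wd %*% V %*% t(wz))
  }
  expect_equal(expected_next_value(pd, pz, t, V, p, g), ev,
               tolerance = 1e-9)
})

test_that("backward induction produces a consistent policy solution", {
  pol <- solve_policy(ref_params(), belief_grid(60, 60))
  D <- pol$params$D
  # V^D equals the closed form exactly
  psD <- prob_stop_trial(pol$grid$centers_z, D, 0.25, 22 / 350)
  expect_equal(pol$value[[D]],
               matrix(terminal_value(psD, ref_params()), 60, 60, byrow = TRUE))
  # V = min(Q_g, Q_w) elementwise; go map marks strict Q_g < Q_w
  for (t in c(1, 10, 30, 49)) {
    expect_true(all(pol$value[[t]] <= pol$q_go_table[[t]] + 1e-12))
    expect_true(all(pol$value[[t]] <= pol$q_wait_table[[t]] + 1e-12))
    expect_identical(pol$go_map[[t]],
                     pol$q_go_table[[t]] < pol$q_wait_table[[t]])
  }
  # mirror symmetry in p_d (cost depends on p_d only via min(p_d, 1-p_d))
  expect_equal(pol$value[[25]], pol$value[[25]][60:1, ], tolerance = 1e-12)
  expect_identical(pol$go_map[[25]], pol$go_map[[25]][60:1, ])
  # deadline pressure: the go region grows over the trial
  areas <- go_region_area(pol, 1:(D - 1))
  expect_true(all(diff(areas) >= 0))
  expect_true(all(areas >= 0 & areas <= 1))
})

test_that("both deadline-step belief conventions coincide", {
  p <- task_params(D = 12)
  g <- belief_grid(40, 40)
  pa <- solve_policy(p, g, deadline_ps = "carried")
  pb <- solve_policy(p, g, deadline_ps = "advanced")
  expect_equal(pa$q_wait_table[[11]], pb$q_wait_table[[11]],
               tolerance = 1e-12)
})

test_that("stop-free limit reduces to a symmetric 2AFC threshold", {
  pol <- solve_policy(task_params(r = 0, q = 0.1, q_d = 0.9, c = 0.002),
                      belief_grid(50, 50))
  # with r = 0 the reachable stop belief is p_z = 0: examine that slice
  row <- pol$go_map[[25]][, 1]
  expect_identical(row, rev(row))               # symmetric about p_d = 0.5
  expect_false(row[25])                          # undecided: wait
  expect_true(row[1] && row[50])                 # confident: go
  # a threshold structure: go exactly outside a central band
  runs <- rle(row)
  expect_identical(runs$values, c(TRUE, FALSE, TRUE))
})

test_that("a prohibitive stop-error penalty empties the early go region", {
  pol <- solve_policy(task_params(c_s = 100), belief_grid(50, 50))
  ps10 <- prob_stop_trial(pol$grid$centers_z, 10, 0.25, 22 / 350)
  risky <- pol$go_map[[10]][, ps10 > 0.02]
  expect_false(any(risky))
})

test_that("cost-free going dominates waiting into certain omission", {
  pol <- solve_policy(task_params(c = 0, c_s = 0, q_d = 0.5, q_s = 0.5),
                      belief_grid(30, 30))
  expect_gte(go_region_area(pol, pol$params$D - 1), 0.99)
})

test_that("action lookup respects the go map and its domain", {
  pol <- solve_policy(ref_params(), belief_grid(60, 60))
  # a central high-stop-belief state waits
  expect_identical(optimal_action(pol, 0.5, 0.9, 25), "wait")
  # consistency with the stored map at an arbitrary cell
  i <- 58; j <- 2; t <- 45
  act <- optimal_action(pol, pol$grid$centers_d[i], pol$grid$centers_z[j], t)
  expect_identical(act, if (pol$go_map[[t]][i, j]) "go" else "wait")
  expect_error(optimal_action(pol, 0.5, 0.5, 50), "t")
  expect_error(optimal_action(pol, 0.5, 0.5, 0), "t")
})

test_that("the DP policy beats fixed-threshold rules on a small instance", {
  p <- task_params(r = 0.25, q = 0.25, q_d = 0.75, q_s = 0.75, D = 3,
                   c = 0.01, c_s = 0.4)
  pol <- solve_policy(p, belief_grid(101, 101))
  dp_decide <- function(t, p_d, p_z) optimal_action(pol, p_d, p_z, t) == "go"
  dp_loss <- enum_expected_loss(dp_decide, p)
  for (phi in c(0.05, 0.15, 0.25, 0.35, 0.45)) {
    for (psi in c(0.1, 0.3, 0.5, 0.9)) {
      th_decide <- function(t, p_d, p_z) {
        ps <- prob_stop_trial(p_z, t, p$r, p$q)
        min(p_d, 1 - p_d) <= phi && ps <= psi
      }
      expect_lte(dp_loss, enum_expected_loss(th_decide, p) + 1e-9)
    }
  }
})

test_that("policy files round-trip through serialization", {
  pol <- solve_policy(task_params(D = 6), belief_grid(10, 10))
  path <- tempfile(fileext = ".rds")
  write_policy(pol, path)
  back <- read_policy(path)
  expect_equal(back, pol)
  saveRDS(list(format = "other"), path)
  expect_error(read_policy(path), "policy file")
})
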