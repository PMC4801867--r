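test_that("condition summaries match hand counts on a toy table", {
  s <- summarize_condition(toy_trials())
  expect_equal(s$median_go_rt_ms, 500)
  expect_equal(s$mean_go_rt_ms, 500)
  expect_equal(s$discrimination_error_rate, 0.25)
  expect_equal(s$omission_error_rate, 0.25)
  expect_equal(s$stop_error_rate, 0.25)
  expect_identical(s$n_go, 4L)
  expect_identical(s$n_stop, 4L)
  # correct-only RT policy drops the wrong-side 600 ms response
  s2 <- summarize_condition(toy_trials(), rt_policy = "correct")
  expect_equal(s2$median_go_rt_ms, 450)
})

test_that("degenerate trial subsets are flagged, not fabricated", {
  tt <- toy_trials()
  # all stop trials responded
  tt2 <- tt
  tt2$response[tt2$trial_type == "stop"] <- "right"
  tt2$rt_ms[tt2$trial_type == "stop"] <- 300
  tt2$outcome[tt2$trial_type == "stop"] <- "stop_error"
  expect_equal(summarize_condition(tt2)$stop_error_rate, 1)
  # empty stop subset: NA with a warning
  go_only <- tt[tt$trial_type == "go", ]
  expect_warning(s <- summarize_condition(go_only), "stop")
  expect_true(is.na(s$stop_error_rate))
  expect_error(summarize_condition(tt[tt$trial_type == "stop", ]), "go trials")
})

test_that("inhibition function reports per-SSD proportions with counts", {
  ih <- inhibition_function(toy_trials())
  expect_equal(ih, data.frame(ssd_ms = 100, se_rate = 0.25, n = 4))
  # all stop successes at every SSD: flat zero function
  tt <- toy_trials()
  tt$outcome[tt$trial_type == "stop"] <- "stop_success"
  tt$response[tt$trial_type == "stop"] <- "none"
  tt$rt_ms[tt$trial_type == "stop"] <- NA
  tt$ssd_ms[tt$trial_type == "stop"] <- c(100, 100, 300, 500)
  ih2 <- inhibition_function(tt)
  expect_equal(ih2$se_rate, c(0, 0, 0))
  expect_equal(ih2$ssd_ms, c(100, 300, 500))   # zero-trial SSDs omitted
  expect_equal(ih2$n, c(2, 1, 1))
})

test_that("SSRT estimation finds the 50% crossing of the fitted curve", {
  pts <- data.frame(ssd_ms = c(100, 200, 300, 400, 500),
                    se_rate = c(0.1, 0.3, 0.5, 0.7, 0.9), n = rep(20, 5))
  est <- estimate_ssrt(pts, median_go_rt_ms = 500)
  expect_equal(est$ssd50_ms, 300, tolerance = 1e-2)
  expect_equal(est$ssrt_ms, 200, tolerance = 1e-2)
  expect_identical(est$flag, "ok")
  # saturated inhibition: crossing pinned to the support edge and flagged
  sat <- data.frame(ssd_ms = c(100, 300, 500), se_rate = rep(1, 3),
                    n = rep(10, 3))
  est_sat <- estimate_ssrt(sat, 500)
  expect_identical(est_sat$flag, "starts_above")
  expect_equal(est_sat$ssd50_ms, 100)
  # flat-zero inhibition: no crossing, flagged NA
  flat <- data.frame(ssd_ms = c(100, 300, 500), se_rate = rep(0, 3),
                     n = rep(10, 3))
  est_flat <- estimate_ssrt(flat, 500)
  expect_identical(est_flat$flag, "no_crossing")
  expect_true(is.na(est_flat$ssrt_ms))
  # contract checks
  expect_error(estimate_ssrt(pts[1:2, ], 500), "3 distinct")
  expect_error(estimate_ssrt(pts, NA), "median_go_rt")
})

test_that("rates of concatenated tables are count-weighted combinations", {
  set.seed(60)
  a <- synth_cohort(n_subjects = 1, n_trials_per_condition = 120, seed = 3)
  b <- synth_cohort(n_subjects = 1, n_trials_per_condition = 80, seed = 4)
  b$subject_id <- "S01"
  for (cd in c("8", "85")) {
    sa <- suppressWarnings(summarize_condition(a, "S01", cd))
    sb <- suppressWarnings(summarize_condition(b, "S01", cd))
    sc <- suppressWarnings(summarize_condition(rbind(a, b), "S01", cd))
    for (m in c("discrimination_error_rate", "omission_error_rate")) {
      expect_equal(sc[[m]],
                   (sa[[m]] * sa$n_go + sb[[m]] * sb$n_go) / (sa$n_go + sb$n_go))
    }
    expect_equal(sc$stop_error_rate,
                 (sa$stop_error_rate * sa$n_stop +
                    sb$stop_error_rate * sb$n_stop) / (sa$n_stop + sb$n_stop))
  }
})

test_that("cohort summaries cover every subject-condition block", {
  trials <- synth_cohort(n_subjects = 4, n_trials_per_condition = 150,
                         seed = 21)
  summ <- summarize_cohort(trials)
  expect_identical(nrow(summ), 4L * 4L)
  expect_true(all(summ$n_go + summ$n_stop == 150L))
  expect_true(all(summ$ssrt_flag %in%
                    c("ok", "starts_above", "no_crossing", "too_few_points")))
  cm <- condition_means(summ, c("8", "15", "85", "X"))
  expect_identical(cm$condition, c("8", "15", "85", "X"))
  expect_true(all(is.finite(cm$mean_go_rt_ms)))
})

test_that("the estimator recovers a known SSRT from race-model cohorts", {
  eff <- data.frame(label = "cal", go_rt_mean_ms = 500, go_rt_sd_ms = 100,
                    ssrt_ms = 200, discrimination_error_prob = 0.05)
  trials <- synth_cohort(n_subjects = 8, n_trials_per_condition = 600,
                         effects = eff, subject_sd_go_rt_ms = 0,
                         subject_sd_ssrt_ms = 0, seed = 9)
  summ <- summarize_cohort(trials)
  expect_true(all(summ$ssrt_flag == "ok"))
  expect_lt(abs(mean(summ$ssrt_ms) - 200), 25)
})
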