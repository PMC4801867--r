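## Classical independent race model of the stop-signal task: a go process
## with a broad finishing-time distribution races a stop process that
## finishes at SSD + SSRT.  Serves both as the comparison baseline and as
## the synthetic-cohort generator with known ground truth.

#' Parameters of the race model
#'
#' The go finishing time has mean `go_rt_mean_ms` and standard deviation
#' `go_rt_sd_ms` (lognormal by default, right-skewed as empirical RTs are;
#' truncated-normal optional).  The stop process finishes at
#' `SSD + SSRT`, with SSRT mean `ssrt_ms` and spread `ssrt_sd_ms` (0 gives
#' the fixed-SSRT model under which the inhibition function has a closed
#' form).  Go finishes after the deadline are censored: omission errors on
#' go trials, stop successes on stop trials.
#'
#' @param go_rt_mean_ms,go_rt_sd_ms Mean and sd of the go finishing time.
#' @param ssrt_ms,ssrt_sd_ms Mean and sd of the stop-process delay.
#' @param discrimination_error_prob Probability a go response is on the
#'   wrong side.
#' @param deadline_ms Response deadline.
#' @param family `"lognormal"` (default) or `"normal"` (truncated at 0).
#' @return An object of class `"race_params"`.
#' @export
race_params <- function(go_rt_mean_ms = 500, go_rt_sd_ms = 100,
                        ssrt_ms = 200, ssrt_sd_ms = 0,
                        discrimination_error_prob = 0.05,
                        deadline_ms = 1100,
                        family = c("lognormal", "normal")) {
  family <- match.arg(family)
  if (go_rt_mean_ms <= 0 || go_rt_sd_ms <= 0)
    stop("go RT mean and sd must be positive", call. = FALSE)
  if (ssrt_ms <= 0 || ssrt_sd_ms < 0)
    stop("'ssrt_ms' must be positive and 'ssrt_sd_ms' non-negative",
         call. = FALSE)
  stop_unless_prob(discrimination_error_prob, "discrimination_error_prob")
  if (deadline_ms <= 0) stop("'deadline_ms' must be positive", call. = FALSE)
  structure(list(go_rt_mean_ms = go_rt_mean_ms, go_rt_sd_ms = go_rt_sd_ms,
                 ssrt_ms = ssrt_ms, ssrt_sd_ms = ssrt_sd_ms,
                 discrimination_error_prob = discrimination_error_prob,
                 deadline_ms = deadline_ms, family = family),
            class = "race_params")
}

## lognormal (meanlog, sdlog) matching a target mean and sd
lnorm_pars <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

sample_go_finish <- function(n, params) {
  if (params$family == "lognormal") {
    lp <- lnorm_pars(params$go_rt_mean_ms, params$go_rt_sd_ms)
    stats::rlnorm(n, lp["meanlog"], lp["sdlog"])
  } else {
    t <- stats::rnorm(n, params$go_rt_mean_ms, params$go_rt_sd_ms)
    while (any(t <= 0)) {                     # truncate at zero
      bad <- t <= 0
      t[bad] <- stats::rnorm(sum(bad), params$go_rt_mean_ms,
                             params$go_rt_sd_ms)
    }
    t
  }
}

go_finish_cdf <- function(t_ms, params) {
  if (params$family == "lognormal") {
    lp <- lnorm_pars(params$go_rt_mean_ms, params$go_rt_sd_ms)
    stats::plnorm(t_ms, lp["meanlog"], lp["sdlog"])
  } else {
    p0 <- stats::pnorm(0, params$go_rt_mean_ms, params$go_rt_sd_ms)
    (stats::pnorm(t_ms, params$go_rt_mean_ms, params$go_rt_sd_ms) - p0) /
      (1 - p0)
  }
}

#' Simulate race-model trials
#'
#' On each trial the go finishing time is sampled from the go distribution;
#' on stop trials the stop process finishes at `SSD + SSRT`.  A response is
#' emitted iff the go process finishes before both the stop process and
#' the deadline; the response is on the wrong side with
#' `discrimination_error_prob`.
#'
#' @param params A [race_params()] object.
#' @param trial_type Character vector, `"go"` or `"stop"`.
#' @param ssd_ms SSDs in ms (`NA` on go trials).
#' @param d Optional latent go-stimulus identities (0/1); sampled
#'   uniformly when omitted.
#' @param subject_id,condition Labels stamped on the records.
#' @return A trial-record data frame (same schema as [simulate_cohort()]).
#' @examples
#' set.seed(1)
#' simulate_race_trials(race_params(), c("go", "stop"), c(NA, 300))
#' @export
simulate_race_trials <- function(params, trial_type, ssd_ms,
                                 d = NULL, subject_id = "S01",
                                 condition = "cond") {
  stopifnot(inherits(params, "race_params"))
  n <- length(trial_type)
  if (length(ssd_ms) != n) stop("'ssd_ms' length mismatch", call. = FALSE)
  is_stop <- trial_type == "stop"
  if (any(is_stop & is.na(ssd_ms)) || any(!is_stop & !is.na(ssd_ms)))
    stop("'ssd_ms' must be present exactly on stop trials", call. = FALSE)
  if (is.null(d)) d <- stats::rbinom(n, 1L, 0.5)
  t_go <- sample_go_finish(n, params)
  ssrt <- if (params$ssrt_sd_ms > 0)
    stats::rnorm(n, params$ssrt_ms, params$ssrt_sd_ms) else
    rep(params$ssrt_ms, n)
  stop_finish <- ifelse(is_stop, ssd_ms + ssrt, Inf)
  responded <- t_go < stop_finish & t_go <= params$deadline_ms
  wrong <- stats::rbinom(n, 1L, params$discrimination_error_prob) == 1L
  side <- ifelse(wrong, 1L - d, d)
  response <- rep("none", n)
  response[responded] <- ifelse(side[responded] == 1L, "right", "left")
  outcome <- character(n)
  outcome[!is_stop & responded & !wrong] <- "go_correct"
  outcome[!is_stop & responded & wrong] <- "discrimination_error"
  outcome[!is_stop & !responded] <- "omission_error"
  outcome[is_stop & responded] <- "stop_error"
  outcome[is_stop & !responded] <- "stop_success"
  data.frame(subject_id = subject_id, condition = condition,
             trial_type = trial_type, ssd_ms = ssd_ms,
             response = response,
             rt_ms = ifelse(responded, t_go, NA_real_),
             outcome = outcome, latent_d = d,
             stringsAsFactors = FALSE)
}

#' Closed-form inhibition function of the fixed-SSRT race model
#'
#' With a fixed stop-process delay, the stop-error rate at a given SSD is
#' the go finishing-time distribution function evaluated at `SSD + SSRT`
#' (censored at the deadline).  In particular it equals 0.5 exactly when
#' `SSD + SSRT` equals the median go finishing time.
#'
#' @param params A [race_params()] with `ssrt_sd_ms = 0`.
#' @param ssd_ms SSD values (vectorized).
#' @return Stop-error probabilities.
#' @examples
#' p <- race_params(go_rt_mean_ms = 500, go_rt_sd_ms = 80, ssrt_ms = 200)
#' analytic_inhibition(p, 400)
#' @export
analytic_inhibition <- function(params, ssd_ms) {
  stopifnot(inherits(params, "race_params"))
  if (params$ssrt_sd_ms != 0)
    stop("closed form requires 'ssrt_sd_ms' = 0", call. = FALSE)
  go_finish_cdf(pmin(ssd_ms + params$ssrt_ms, params$deadline_ms), params)
}

#' Median of the go finishing-time distribution
#'
#' @param params A [race_params()] object.
#' @return Median go finishing time in ms (no deadline censoring).
#' @export
race_median_go_rt <- function(params) {
  stopifnot(inherits(params, "race_params"))
  if (params$family == "lognormal") {
    unname(exp(lnorm_pars(params$go_rt_mean_ms, params$go_rt_sd_ms)["meanlog"]))
  } else {
    params$go_rt_mean_ms                         # symmetric before truncation
  }
}

#' Default condition effects for the synthetic human cohort
#'
#' Per-condition race parameters emulating the four go-discriminability
#' conditions of the human experiment (8%, 15%, 85% motion coherence, and
#' a shape task of comparable difficulty to 85%): go RT, SSRT and
#' discrimination errors all decrease as the go stimulus gets easier.
#'
#' @return Data frame with one row per condition.
#' @export
synth_condition_effects <- function() {
  data.frame(
    label = c("8", "15", "85", "X"),
    go_rt_mean_ms = c(580, 560, 500, 490),
    go_rt_sd_ms = c(180, 170, 150, 145),
    ssrt_ms = c(230, 220, 200, 195),
    discrimination_error_prob = c(0.20, 0.12, 0.03, 0.02),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic human cohort from the race model
#'
#' Emulates the human experiment's structure — by default 20 subjects, 4
#' conditions, 225 trials per condition (3 blocks of 75), 25% stop trials
#' with SSDs balanced over \{100, ..., 600\} ms — with known per-subject
#' race parameters, so every downstream stage (summaries, SSRT estimation,
#' paired tests) can be validated against ground truth.
#'
#' Subject heterogeneity adds Gaussian offsets to each subject's go RT
#' mean and SSRT, shared across conditions (so condition effects are
#' within-subject, as in the experiment).
#'
#' @param n_subjects Number of subjects.
#' @param n_trials_per_condition Trials per subject and condition.
#' @param effects Per-condition parameters, as from
#'   [synth_condition_effects()].
#' @param subject_sd_go_rt_ms,subject_sd_ssrt_ms Between-subject standard
#'   deviations (0 gives identical subjects).
#' @param ssrt_sd_ms Within-trial SSRT spread.
#' @param stop_fraction Fraction of stop trials.
#' @param ssd_values_ms SSD grid.
#' @param deadline_ms Response deadline.
#' @param seed Integer root seed; per-subject streams are derived from it.
#' @return A trial-record data frame
#'   (`n_subjects * nrow(effects) * n_trials_per_condition` rows).
#' @examples
#' trials <- synth_cohort(n_subjects = 2, n_trials_per_condition = 40, seed = 1)
#' table(trials$condition, trials$trial_type)
#' @export
synth_cohort <- function(n_subjects = 20L, n_trials_per_condition = 225L,
                         effects = synth_condition_effects(),
                         subject_sd_go_rt_ms = 30, subject_sd_ssrt_ms = 12,
                         ssrt_sd_ms = 0, stop_fraction = 0.25,
                         ssd_values_ms = seq(100, 600, by = 100),
                         deadline_ms = 1100, seed = 1L) {
  out <- vector("list", n_subjects * nrow(effects))
  k <- 0L
  for (sj in seq_len(n_subjects)) {
    seed_sj <- (seed + 7919L * sj) %% 2147483647L
    set.seed(seed_sj)
    off_rt <- stats::rnorm(1, 0, subject_sd_go_rt_ms)
    off_ssrt <- stats::rnorm(1, 0, subject_sd_ssrt_ms)
    for (ci in seq_len(nrow(effects))) {
      p <- race_params(
        go_rt_mean_ms = effects$go_rt_mean_ms[ci] + off_rt,
        go_rt_sd_ms = effects$go_rt_sd_ms[ci],
        ssrt_ms = max(50, effects$ssrt_ms[ci] + off_ssrt),
        ssrt_sd_ms = ssrt_sd_ms,
        discrimination_error_prob = effects$discrimination_error_prob[ci],
        deadline_ms = deadline_ms)
      n <- n_trials_per_condition
      n_stop <- round(stop_fraction * n)
      trial_type <- rep("go", n)
      trial_type[sample.int(n, n_stop)] <- "stop"
      ssd <- rep(NA_real_, n)
      ssd[trial_type == "stop"] <-
        rep(ssd_values_ms, length.out = n_stop)[sample.int(n_stop)]
      k <- k + 1L
      out[[k]] <- simulate_race_trials(p, trial_type, ssd,
                                       subject_id = sprintf("S%02d", sj),
                                       condition = effects$label[ci])
    }
  }
  do.call(rbind, out)
}
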