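## Cohort simulation of ideal-observer subjects performing the stop-signal
## task.  The belief recursion is advanced for all trials of a subject in
## lock-step; a trial terminates the first time its belief lands in a Go
## cell of the policy map, or at the deadline.

#' Experimental-design configuration for simulated cohorts
#'
#' Encodes the task timing and design used by [simulate_cohort()] and
#' [synth_cohort()].  Defaults follow the human experiment the model
#' emulates: 1100 ms response deadline, stop signals on 25% of trials,
#' stop-signal delays (SSDs) drawn from \{100, ..., 600\} ms.
#'
#' @param dt_ms Milliseconds per model time step.  With the default 50-step
#'   deadline this is `1100 / 50 = 22` ms.
#' @param deadline_ms Response deadline in ms.
#' @param ssd_mode `"empirical"` draws SSDs from `ssd_values_ms` (as in the
#'   experiment); `"geometric"` samples the onset step from the observer's
#'   geometric prior.
#' @param ssd_values_ms SSD grid in ms for the empirical mode.
#' @param stop_fraction Fraction of stop trials.
#' @param stop_allocation `"stratified"` gives every subject an exact stop
#'   count with SSDs balanced over the grid (blocked designs);
#'   `"bernoulli"` samples trial types independently.
#' @param n_subjects,n_trials_per_subject Cohort size per condition.
#' @param conditions Data frame with columns `label` and `q_d`, one row per
#'   go-discriminability condition.
#' @param non_decision_ms Constant motor offset added to simulated RTs.
#' @param root_seed Integer seed from which per-subject, per-condition
#'   streams are derived deterministically.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(dt_ms = 22, deadline_ms = 1100,
                       ssd_mode = c("empirical", "geometric"),
                       ssd_values_ms = seq(100, 600, by = 100),
                       stop_fraction = 0.25,
                       stop_allocation = c("stratified", "bernoulli"),
                       n_subjects = 20L, n_trials_per_subject = 300L,
                       conditions = data.frame(
                         label = c("low", "mid", "high"),
                         q_d = c(0.55, 0.62, 0.70)),
                       non_decision_ms = 0, root_seed = 1L) {
  ssd_mode <- match.arg(ssd_mode)
  stop_allocation <- match.arg(stop_allocation)
  if (dt_ms <= 0) stop("'dt_ms' must be positive", call. = FALSE)
  if (deadline_ms <= 0) stop("'deadline_ms' must be positive", call. = FALSE)
  stop_unless_prob(stop_fraction, "stop_fraction")
  if (any(ssd_values_ms <= 0 | ssd_values_ms >= deadline_ms))
    stop("'ssd_values_ms' must lie within (0, deadline_ms)", call. = FALSE)
  if (!is.data.frame(conditions) ||
      !all(c("label", "q_d") %in% names(conditions)))
    stop("'conditions' needs columns 'label' and 'q_d'", call. = FALSE)
  if (anyDuplicated(conditions$label))
    stop("condition labels must be unique", call. = FALSE)
  structure(list(dt_ms = dt_ms, deadline_ms = deadline_ms,
                 ssd_mode = ssd_mode, ssd_values_ms = ssd_values_ms,
                 stop_fraction = stop_fraction,
                 stop_allocation = stop_allocation,
                 n_subjects = as.integer(n_subjects),
                 n_trials_per_subject = as.integer(n_trials_per_subject),
                 conditions = conditions,
                 non_decision_ms = non_decision_ms,
                 root_seed = as.integer(root_seed)),
            class = "sim_config")
}

#' Convert between milliseconds and model time steps
#'
#' Steps are `round(ms / dt_ms)`; the reverse map is exact, so round trips
#' are stable for multiples of `dt_ms` and otherwise land on the nearest
#' step boundary.
#'
#' @param ms,steps Values to convert (non-negative).
#' @param dt_ms Milliseconds per step.
#' @return Converted values.
#' @examples
#' ms_to_steps(1100, 22)           # 50
#' steps_to_ms(ms_to_steps(300, 22), 22)   # 308: documented rounding
#' @export
ms_to_steps <- function(ms, dt_ms) {
  if (any(ms < 0) || dt_ms <= 0) stop("times must be non-negative and dt_ms > 0",
                                      call. = FALSE)
  as.integer(round(ms / dt_ms))
}

#' @rdname ms_to_steps
#' @export
steps_to_ms <- function(steps, dt_ms) {
  if (any(steps < 0) || dt_ms <= 0) stop("times must be non-negative and dt_ms > 0",
                                         call. = FALSE)
  steps * dt_ms
}

## Vectorized trial engine: advances all trials in lock-step.
## d, s: integer vectors; theta: onset step (NA on go trials).
run_trials <- function(policy, d, s, theta, config,
                       subject_id, condition_label, ssd_ms) {
  params <- policy$params
  D <- params$D
  if (ms_to_steps(config$deadline_ms, config$dt_ms) != D)
    stop("policy deadline (D) inconsistent with config dt_ms/deadline_ms",
         call. = FALSE)
  n <- length(d)
  n_d <- policy$grid$n_d; n_z <- policy$grid$n_z
  p_d <- rep(params$p_d_prior, n)
  p_z <- numeric(n)
  resp_step <- rep(NA_integer_, n)
  resp_side <- rep(NA_integer_, n)
  active <- rep(TRUE, n)
  for (t in seq_len(D - 1L)) {
    idx <- which(active)
    if (!length(idx)) break
    z <- s[idx] == 1L & t >= theta[idx]
    z[is.na(z)] <- FALSE
    x <- stats::rbinom(length(idx), 1L,
                       ifelse(d[idx] == 1L, params$q_d, 1 - params$q_d))
    y <- stats::rbinom(length(idx), 1L,
                       ifelse(z, params$q_s, 1 - params$q_s))
    p_d[idx] <- update_pd(p_d[idx], x, params$q_d)
    p_z[idx] <- update_pz(p_z[idx], y, t, params)
    cell <- cbind(belief_cell(p_d[idx], n_d), belief_cell(p_z[idx], n_z))
    going <- policy$go_map[[t]][cell]
    if (any(going)) {
      gi <- idx[going]
      resp_step[gi] <- t
      pd_g <- p_d[gi]
      side <- integer(length(gi))
      side[pd_g > 0.5] <- 1L
      tie <- pd_g == 0.5
      if (any(tie)) side[tie] <- stats::rbinom(sum(tie), 1L, 0.5)
      resp_side[gi] <- side
      active[gi] <- FALSE
    }
  }
  responded <- !is.na(resp_step)
  rt <- rep(NA_real_, n)
  rt[responded] <- steps_to_ms(resp_step[responded], config$dt_ms) +
    config$non_decision_ms
  response <- rep("none", n)
  response[responded] <- ifelse(resp_side[responded] == 1L, "right", "left")
  outcome <- character(n)
  go_tr <- s == 0L
  outcome[go_tr & responded & resp_side == d] <- "go_correct"
  outcome[go_tr & responded & resp_side != d] <- "discrimination_error"
  outcome[go_tr & !responded] <- "omission_error"
  outcome[!go_tr & responded] <- "stop_error"
  outcome[!go_tr & !responded] <- "stop_success"
  data.frame(subject_id = subject_id,
             condition = condition_label,
             trial_type = ifelse(go_tr, "go", "stop"),
             ssd_ms = ssd_ms,
             response = response,
             rt_ms = rt,
             outcome = outcome,
             latent_d = d,
             stringsAsFactors = FALSE)
}

## Draw latent structure (s, theta, ssd_ms, d) for one subject-condition run.
draw_latents <- function(n, config, params) {
  if (config$stop_allocation == "stratified") {
    n_stop <- round(config$stop_fraction * n)
    is_stop <- rep(FALSE, n)
    is_stop[sample.int(n, n_stop)] <- TRUE
  } else {
    is_stop <- stats::rbinom(n, 1L, config$stop_fraction) == 1L
    n_stop <- sum(is_stop)
  }
  ssd <- rep(NA_real_, n)
  theta <- rep(NA_integer_, n)
  if (n_stop > 0) {
    if (config$ssd_mode == "empirical") {
      vals <- config$ssd_values_ms
      pool <- rep(vals, length.out = n_stop)        # balanced over the grid
      pool <- pool[sample.int(n_stop)]
      ssd[is_stop] <- pool
      theta[is_stop] <- pmax(1L, ms_to_steps(pool, config$dt_ms))
    } else {
      th <- sample_theta(n_stop, params$q)
      theta[is_stop] <- th
      ssd[is_stop] <- steps_to_ms(th, config$dt_ms)
    }
  }
  d <- stats::rbinom(n, 1L, params$p_d_prior)
  list(d = d, s = as.integer(is_stop), theta = theta, ssd_ms = ssd)
}

#' Simulate a single stop-signal trial under an optimal policy
#'
#' Runs the belief recursion on freshly sampled observations step by step;
#' the trial ends with a response the first time the belief enters a Go
#' region of the policy, otherwise at the deadline.
#'
#' @param policy A [solve_policy()] result.
#' @param latents A [trial_latents()] object (onset step `theta` is in
#'   model steps).
#' @param config A [sim_config()] consistent with the policy's deadline.
#' @return A one-row trial-record data frame (see [simulate_cohort()]).
#' @examples
#' pol <- solve_policy(task_params(D = 10), belief_grid(25, 25))
#' cfg <- sim_config(dt_ms = 110, deadline_ms = 1100)
#' set.seed(1)
#' simulate_trial(pol, trial_latents(1, 0), cfg)
#' @export
simulate_trial <- function(policy, latents, config) {
  stopifnot(inherits(policy, "stop_policy"), inherits(latents, "trial_latents"),
            inherits(config, "sim_config"))
  ssd <- if (latents$s == 1L) steps_to_ms(latents$theta, config$dt_ms)
         else NA_real_
  run_trials(policy, latents$d, latents$s,
             if (is.null(latents$theta)) NA_integer_ else latents$theta,
             config, "S01", "cond", ssd)
}

#' Simulate a cohort of optimal-observer subjects
#'
#' Simulates every subject in every go-discriminability condition of the
#' design.  Each subject-condition block gets its own RNG stream derived
#' deterministically from `config$root_seed`, so runs are reproducible and
#' invariant to block ordering.
#'
#' @param policies Named list of [solve_policy()] results, one per
#'   condition label in `config$conditions`; the policies differ in `q_d`
#'   and share all other parameters.
#' @param config A [sim_config()].
#' @return A trial-record data frame with columns `subject_id`,
#'   `condition`, `trial_type`, `ssd_ms`, `response`, `rt_ms`, `outcome`,
#'   `latent_d`.
#' @export
simulate_cohort <- function(policies, config) {
  stopifnot(inherits(config, "sim_config"))
  labels <- config$conditions$label
  if (!all(labels %in% names(policies)))
    stop("'policies' must be a named list covering every condition label",
         call. = FALSE)
  out <- vector("list", config$n_subjects * length(labels))
  k <- 0L
  for (ci in seq_along(labels)) {
    pol <- policies[[labels[ci]]]
    stopifnot(inherits(pol, "stop_policy"))
    for (sj in seq_len(config$n_subjects)) {
      seed <- (config$root_seed + 104729L * ci + 7919L * sj) %% 2147483647L
      set.seed(seed)
      lat <- draw_latents(config$n_trials_per_subject, config, pol$params)
      k <- k + 1L
      out[[k]] <- run_trials(pol, lat$d, lat$s, lat$theta, config,
                             sprintf("S%02d", sj), labels[ci], lat$ssd_ms)
    }
  }
  do.call(rbind, out)
}

#' Simulate trials from a solved policy
#'
#' `simulate` method for `stop_policy`: draws `nsim` trials of a single
#' model subject under the policy's own parameters (stop fraction, SSD
#' design and timing taken from `config`).
#'
#' @param object A [solve_policy()] result.
#' @param nsim Number of trials.
#' @param seed Optional integer seed.
#' @param config A [sim_config()].
#' @param ... Unused.
#' @return A trial-record data frame with `nsim` rows.
#' @export
simulate.stop_policy <- function(object, nsim = 100, seed = NULL,
                                 config = sim_config(), ...) {
  if (!is.null(seed)) set.seed(seed)
  lat <- draw_latents(nsim, config, object$params)
  run_trials(object, lat$d, lat$s, lat$theta, config,
             "S01", "cond", lat$ssd_ms)
}
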