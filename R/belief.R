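## Iterative Bayesian belief updates for the stop-signal ideal observer.
##
## The observer tracks two posteriors across the trial:
##   p_d = P(d = 1 | x^1..x^t)   go-stimulus identity
##   p_z = P(stop signal has onset by t | y^1..y^t)
## and derives p_s = P(stop trial | y^1..y^t) from (p_z, t).
## Evidence is binary and conditionally iid; the onset step is geometric.

.EPS <- 1e-12

#' One-step posterior update for the go-stimulus identity
#'
#' Applies Bayes' rule to the running posterior `p_d = P(d = 1 | data)`
#' given one binary evidence sample `x`.  Under `d = 1` a sample equals 1
#' with probability `q_d`; under `d = 0` with probability `1 - q_d`.
#'
#' @param p_d Current posterior probability that `d = 1` (vectorized).
#' @param x Binary observation(s), 0 or 1.
#' @param q_d Go-evidence reliability in \[0.5, 1\].
#' @return Updated posterior probability, same length as the inputs.
#' @examples
#' update_pd(0.5, 1, 0.7)   # 0.7
#' update_pd(0.5, 0, 0.5)   # uninformative evidence: stays 0.5
#' @export
update_pd <- function(p_d, x, q_d) {
  if (any(p_d < 0 | p_d > 1, na.rm = FALSE))
    stop("'p_d' must lie in [0, 1]", call. = FALSE)
  if (!all(x %in% c(0, 1))) stop("'x' must be binary", call. = FALSE)
  stop_unless_reliability(q_d, "q_d")
  f1 <- ifelse(x == 1, q_d, 1 - q_d)
  f0 <- ifelse(x == 1, 1 - q_d, q_d)
  num <- p_d * f1
  den <- num + (1 - p_d) * f0
  ifelse(den < .EPS, p_d, num / den)
}

#' Onset hazard of the stop signal
#'
#' Posterior probability that the stop signal onsets at step `t` given that
#' it has not onset through `t - 1` (marginalizing over whether the trial
#' is a stop trial at all):
#' `h(t) = r q (1-q)^(t-1) / (r (1-q)^(t-1) + (1-r))`.
#'
#' @param t Time step (integer >= 1, vectorized).
#' @param r Prior stop-trial probability.
#' @param q Geometric onset hazard.
#' @return Hazard probability in \[0, 1\].
#' @examples
#' hazard(1, r = 0.25, q = 0.1)   # r * q = 0.025
#' hazard(10, r = 1, q = 0.1)     # memoryless when a stop trial is certain
#' @export
hazard <- function(t, r, q) {
  if (any(t < 1 | t != round(t))) stop("'t' must be integer >= 1", call. = FALSE)
  stop_unless_prob(r, "r")
  surv <- (1 - q)^(t - 1)
  r * q * surv / (r * surv + (1 - r))
}

#' One-step posterior update for stop-signal presence
#'
#' Updates `p_z = P(signal has onset | data)` with one binary stop-evidence
#' sample `y` observed at step `t`.  The prior for the step folds in the
#' onset hazard `h(t)`; after onset samples equal 1 with probability `q_s`,
#' before onset with probability `1 - q_s`.
#'
#' @param p_z Current posterior that the signal has onset (vectorized).
#' @param y Binary observation(s), 0 or 1.
#' @param t Time step of the observation (integer >= 1).
#' @param params A [task_params()] object (uses `r`, `q`, `q_s`).
#' @return Updated posterior probability.
#' @examples
#' p <- task_params(r = 0.25, q = 0.1, q_s = 0.72)
#' update_pz(0, 1, 1, p)   # about 0.0619
#' @export
update_pz <- function(p_z, y, t, params) {
  if (any(p_z < 0 | p_z > 1)) stop("'p_z' must lie in [0, 1]", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("'y' must be binary", call. = FALSE)
  stopifnot(inherits(params, "task_params"))
  h <- hazard(t, params$r, params$q)
  pri <- p_z + (1 - p_z) * h
  g1 <- ifelse(y == 1, params$q_s, 1 - params$q_s)
  g0 <- ifelse(y == 1, 1 - params$q_s, params$q_s)
  num <- g1 * pri
  den <- num + g0 * (1 - p_z) * (1 - h)
  ifelse(den < .EPS, pri, num / den)
}

#' Posterior probability that the current trial is a stop trial
#'
#' Combines the onset posterior `p_z` with the probability that the trial
#' is a stop trial whose signal has not yet onset:
#' `p_s = p_z + (1 - p_z) * r (1-q)^t / (r (1-q)^t + (1-r))`.
#' `p_s >= p_z` always, and before any evidence (`p_z = 0`, `t = 0`)
#' `p_s = r`.
#'
#' @param p_z Posterior that the signal has onset (vectorized).
#' @param t Current time step (integer >= 0).
#' @param r Prior stop-trial probability.
#' @param q Geometric onset hazard.
#' @return Posterior stop-trial probability.
#' @examples
#' prob_stop_trial(0, 0, r = 0.25, q = 0.1)   # the prior r
#' @export
prob_stop_trial <- function(p_z, t, r, q) {
  if (any(p_z < 0 | p_z > 1)) stop("'p_z' must lie in [0, 1]", call. = FALSE)
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  stop_unless_prob(r, "r")
  surv <- (1 - q)^t
  w <- r * surv / (r * surv + (1 - r))
  p_z + (1 - p_z) * w
}

#' Sample stop-signal onset steps from the geometric prior
#'
#' @param n Number of samples.
#' @param q Geometric hazard; the mean onset step is `1/q`.
#' @return Integer vector of onset steps (>= 1).
#' @examples
#' set.seed(1); mean(sample_theta(1e4, 0.1))   # close to 10
#' @export
sample_theta <- function(n, q) {
  if (q <= 0 || q >= 1) stop("'q' must be in (0, 1)", call. = FALSE)
  stats::rgeom(n, q) + 1L
}

#' Sample an observation stream for one trial
#'
#' Draws the binary go- and stop-evidence sequences implied by the trial's
#' latent variables: `x^t` is Bernoulli with rate `q_d` (`d = 1`) or
#' `1 - q_d` (`d = 0`); `y^t` is Bernoulli with rate `q_s` at and after the
#' onset step on stop trials and `1 - q_s` otherwise.
#'
#' @param latents A [trial_latents()] object.
#' @param params A [task_params()] object.
#' @param horizon Number of steps to sample (defaults to `params$D`).
#' @return A data frame with integer columns `x` and `y`, one row per step.
#' @examples
#' p <- task_params()
#' set.seed(1)
#' sample_observations(trial_latents(1, 1, theta = 3), p, horizon = 6)
#' @export
sample_observations <- function(latents, params, horizon = params$D) {
  stopifnot(inherits(latents, "trial_latents"),
            inherits(params, "task_params"))
  if (horizon < 1 || horizon > params$D)
    stop("'horizon' must be in [1, D]", call. = FALSE)
  t <- seq_len(horizon)
  px <- if (latents$d == 1) params$q_d else 1 - params$q_d
  z <- if (latents$s == 1) t >= latents$theta else rep(FALSE, horizon)
  py <- ifelse(z, params$q_s, 1 - params$q_s)
  data.frame(x = stats::rbinom(horizon, 1L, px),
             y = stats::rbinom(horizon, 1L, py))
}

#' Exact posterior by enumeration (test oracle)
#'
#' Computes `(p_d, p_z, p_s)` after observing the sequences `xs`, `ys` by
#' summing the joint model over all latent configurations: `d` in \{0,1\},
#' and the stop side over go trial, stop trial with onset at each step
#' `1..T`, and stop trial with onset beyond `T`.  Independent of the
#' recursive updates; intended as a brute-force cross-check, so it refuses
#' long sequences.
#'
#' @param xs,ys Binary vectors of equal length `T <= 14` (may be empty).
#' @param params A [task_params()] object.
#' @return Named numeric vector with elements `p_d`, `p_z`, `p_s`.
#' @examples
#' p <- task_params()
#' posterior_oracle(integer(0), integer(0), p)   # the priors
#' @export
posterior_oracle <- function(xs, ys, params) {
  stopifnot(inherits(params, "task_params"))
  if (length(xs) != length(ys))
    stop("'xs' and 'ys' must have equal length", call. = FALSE)
  T <- length(xs)
  if (T > 14) stop("sequence too long for enumeration (T > 14)", call. = FALSE)
  if (T && (!all(xs %in% c(0, 1)) || !all(ys %in% c(0, 1))))
    stop("observations must be binary", call. = FALSE)
  xs <- unname(xs); ys <- unname(ys)
  r <- params$r; q <- params$q; qd <- params$q_d; qs <- params$q_s
  p1 <- params$p_d_prior

  ## go-stimulus side: d and x are independent of (s, theta, y)
  if (T == 0) {
    p_d <- p1
  } else {
    l1 <- prod(ifelse(xs == 1, qd, 1 - qd))
    l0 <- prod(ifelse(xs == 1, 1 - qd, qd))
    p_d <- p1 * l1 / (p1 * l1 + (1 - p1) * l0)
  }

  ## stop side: weight every (s, theta) configuration by prior x likelihood
  g1 <- ifelse(ys == 1, qs, 1 - qs)
  g0 <- ifelse(ys == 1, 1 - qs, qs)
  w_go <- (1 - r) * prod(g0)                      # s = 0
  w_onset <- numeric(T)                           # s = 1, theta = k <= T
  for (k in seq_len(T)) {
    lik <- prod(g0[seq_len(k - 1)]) * prod(g1[k:T])
    w_onset[k] <- r * q * (1 - q)^(k - 1) * lik
  }
  w_late <- r * (1 - q)^T * prod(g0)              # s = 1, theta > T
  total <- w_go + sum(w_onset) + w_late
  p_z <- sum(w_onset) / total
  p_s <- (sum(w_onset) + w_late) / total
  c(p_d = p_d, p_z = p_z, p_s = p_s)
}

#' Run the recursive belief updates over full observation sequences
#'
#' Convenience driver: applies [update_pd()] and [update_pz()] step by step
#' and derives `p_s` at the final step.  Used to compare the recursion with
#' [posterior_oracle()].
#'
#' @param xs,ys Binary vectors of equal length.
#' @param params A [task_params()] object.
#' @return Named numeric vector with elements `p_d`, `p_z`, `p_s`.
#' @export
belief_trajectory_end <- function(xs, ys, params) {
  stopifnot(inherits(params, "task_params"))
  xs <- unname(xs); ys <- unname(ys)
  p_d <- params$p_d_prior
  p_z <- 0
  T <- length(xs)
  for (t in seq_len(T)) {
    p_d <- update_pd(p_d, xs[t], params$q_d)
    p_z <- update_pz(p_z, ys[t], t, params)
  }
  c(p_d = p_d, p_z = p_z,
    p_s = prob_stop_trial(p_z, T, params$r, params$q))
}
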