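#' Task and observer parameters for the stop-signal ideal observer
#'
#' Bundles the generative-model and cost parameters governing one condition
#' of the stop-signal task, expressed in model time steps.  All error costs
#' are normalized to the go-error cost, so `c` and `c_s` are in go-error
#' units.
#'
#' @param r Prior probability that a trial is a stop trial, in \[0, 1\].
#' @param q Per-step geometric hazard of stop-signal onset, in (0, 1).  The
#'   observer assumes the onset step follows a geometric distribution with
#'   success probability `q`, so the expected onset step is `1/q`.
#' @param q_d Reliability of each binary go-evidence sample, in \[0.5, 1\]:
#'   under go-stimulus identity `d = 1` each sample equals 1 with
#'   probability `q_d` (and symmetrically for `d = 0`).  Values near 0.5
#'   model hard (low-coherence) discriminations; values near 1 easy ones.
#' @param q_s Reliability of each binary stop-evidence sample, in \[0.5, 1\]:
#'   after stop-signal onset each sample equals 1 with probability `q_s`,
#'   before onset with probability `1 - q_s`.
#' @param D Response deadline in time steps (integer, at least 2).  No
#'   action can be taken at `t = D`; waiting until the deadline constitutes
#'   a stop response.
#' @param c Cost per time step of response delay, non-negative.
#' @param c_s Penalty for responding on a stop trial, non-negative.
#' @param p_d_prior Prior probability that `d = 1`; the task is a
#'   symmetric 2AFC so the default is 0.5.
#'
#' @return An object of class `"task_params"` (a named list).
#' @examples
#' task_params()                      # defaults of the reference condition
#' task_params(q_d = 0.55)           # a harder go discrimination
#' @export
task_params <- function(r = 0.25, q = 22 / 350, q_d = 0.62, q_s = 0.72,
                        D = 50L, c = 0.002, c_s = 0.4, p_d_prior = 0.5) {
  stop_unless_prob(r, "r")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("'q' must be a single number in (0, 1)", call. = FALSE)
  stop_unless_reliability(q_d, "q_d")
  stop_unless_reliability(q_s, "q_s")
  if (!is.numeric(D) || length(D) != 1L || D != round(D) || D < 2)
    stop("'D' must be an integer >= 2", call. = FALSE)
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c < 0)
    stop("'c' must be a finite non-negative number", call. = FALSE)
  if (!is.numeric(c_s) || length(c_s) != 1L || !is.finite(c_s) || c_s < 0)
    stop("'c_s' must be a finite non-negative number", call. = FALSE)
  stop_unless_prob(p_d_prior, "p_d_prior")
  structure(
    list(r = r, q = q, q_d = q_d, q_s = q_s, D = as.integer(D),
         c = c, c_s = c_s, p_d_prior = p_d_prior),
    class = "task_params"
  )
}

#' @export
print.task_params <- function(x, ...) {
  cat("Stop-signal task parameters\n")
  cat(sprintf("  stop-trial prior r      : %.4g\n", x$r))
  cat(sprintf("  onset hazard q          : %.4g  (E[onset] = %.1f steps)\n",
              x$q, 1 / x$q))
  cat(sprintf("  go reliability q_d      : %.4g\n", x$q_d))
  cat(sprintf("  stop reliability q_s    : %.4g\n", x$q_s))
  cat(sprintf("  deadline D              : %d steps\n", x$D))
  cat(sprintf("  delay cost c            : %.4g per step\n", x$c))
  cat(sprintf("  stop-error penalty c_s  : %.4g\n", x$c_s))
  invisible(x)
}

#' Latent variables of one stop-signal trial
#'
#' @param d Go-stimulus identity, 0 or 1.
#' @param s Stop-trial indicator, 0 or 1.
#' @param theta Stop-signal onset step (integer >= 1); must be supplied
#'   exactly when `s = 1`.  The signal is present (`z^t = 1`) at every step
#'   `t >= theta`.
#'
#' @return An object of class `"trial_latents"`.
#' @examples
#' trial_latents(d = 1, s = 0)
#' trial_latents(d = 0, s = 1, theta = 5)
#' @export
trial_latents <- function(d, s, theta = NULL) {
  if (!d %in% c(0, 1)) stop("'d' must be 0 or 1", call. = FALSE)
  if (!s %in% c(0, 1)) stop("'s' must be 0 or 1", call. = FALSE)
  if (s == 1) {
    if (is.null(theta) || !is.numeric(theta) || length(theta) != 1L ||
        theta != round(theta) || theta < 1)
      stop("on a stop trial 'theta' must be an integer >= 1", call. = FALSE)
    theta <- as.integer(theta)
  } else if (!is.null(theta)) {
    stop("'theta' must be absent on a go trial (s = 0)", call. = FALSE)
  }
  structure(list(d = as.integer(d), s = as.integer(s), theta = theta),
            class = "trial_latents")
}

stop_unless_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  invisible(TRUE)
}

stop_unless_reliability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0.5 || x > 1)
    stop(sprintf("'%s' must be a single number in [0.5, 1]", name),
         call. = FALSE)
  invisible(TRUE)
}
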