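# Shared fixtures and independent oracles used across test files.

# reference parameters (the default condition set)
ref_params <- function(...) task_params(...)

# a small hand-built trial table: 4 go trials (RTs 400/500/600/none, sides
# correct/correct/wrong/-) and 4 stop trials at SSD 100 (1 SE, 3 SS)
toy_trials <- function() {
  data.frame(
    subject_id = "S01",
    condition = "A",
    trial_type = c(rep("go", 4), rep("stop", 4)),
    ssd_ms = c(rep(NA_real_, 4), rep(100, 4)),
    response = c("right", "left", "right", "none", "right", rep("none", 3)),
    rt_ms = c(400, 500, 600, NA, 350, NA, NA, NA),
    outcome = c("go_correct", "go_correct", "discrimination_error",
                "omission_error", "stop_error", rep("stop_success", 3)),
    latent_d = c(1L, 0L, 0L, 1L, 1L, 0L, 1L, 0L),
    stringsAsFactors = FALSE
  )
}

# random draw of valid task parameters
random_params <- function() {
  task_params(r = runif(1, 0.05, 0.6), q = runif(1, 0.02, 0.3),
              q_d = runif(1, 0.55, 0.95), q_s = runif(1, 0.55, 0.95),
              D = 50L)
}

# Exhaustive expected loss of an arbitrary decision rule, by enumerating
# every latent configuration and every observation path.  `decide(t, p_d,
# p_z)` returns TRUE to respond.  Completely independent of the dynamic-
# programming solver (uses only the belief recursion and the task's loss).
enum_expected_loss <- function(decide, params) {
  D <- params$D
  r <- params$r; q <- params$q
  qd <- params$q_d; qs <- params$q_s
  configs <- list(list(s = 0L, theta = Inf, w = 1 - r))
  for (k in seq_len(D)) {
    configs[[length(configs) + 1L]] <-
      list(s = 1L, theta = k, w = r * q * (1 - q)^(k - 1))
  }
  configs[[length(configs) + 1L]] <- list(s = 1L, theta = Inf,
                                          w = r * (1 - q)^D)
  steps <- D - 1L
  paths <- as.matrix(expand.grid(rep(list(0:1), 2 * steps)))
  total <- 0
  for (d in 0:1) {
    for (cf in configs) {
      w0 <- 0.5 * cf$w
      for (pi in seq_len(nrow(paths))) {
        xs <- paths[pi, seq_len(steps)]
        ys <- paths[pi, steps + seq_len(steps)]
        prob <- 1
        p_d <- params$p_d_prior; p_z <- 0
        loss <- NA
        for (t in seq_len(steps)) {
          px <- if (d == 1) qd else 1 - qd
          z <- cf$s == 1L && t >= cf$theta
          py <- if (z) qs else 1 - qs
          # full path probability is accumulated over every step so that
          # continuations of a decided prefix sum to the prefix mass
          prob <- prob * (if (xs[t] == 1) px else 1 - px) *
            (if (ys[t] == 1) py else 1 - py)
          if (is.na(loss)) {
            p_d <- update_pd(p_d, xs[t], qd)
            p_z <- update_pz(p_z, ys[t], t, params)
            if (decide(t, p_d, p_z)) {
              delta <- if (p_d > 0.5) 1L else if (p_d < 0.5) 0L else NA
              derr <- if (is.na(delta)) 0.5 else as.numeric(delta != d)
              loss <- params$c * t + params$c_s * (cf$s == 1L) +
                (cf$s == 0L) * derr
            }
          }
        }
        if (is.na(loss)) loss <- params$c * D + (cf$s == 0L)
        total <- total + w0 * prob * loss
      }
    }
  }
  total
}
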