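## Backward-induction solution of the belief-state Markov decision process.
##
## The belief state is (p_d, p_z); p_s is a deterministic function of
## (p_z, t) and is derived wherever needed rather than gridded.  The value
## function and Go/Wait Q-factors are computed on a discretized grid,
## backward from the response deadline.

#' Discretization grid over the (p_d, p_z) belief space
#'
#' Cells have centers at `(i - 0.5)/n`, so the grid covers \[0, 1\] in each
#' coordinate without placing centers on the boundary.
#'
#' @param n_d,n_z Number of bins along `p_d` and `p_z` (>= 2 each; the
#'   reference resolution is 200 x 200).
#' @return An object of class `"belief_grid"` with the bin centers.
#' @examples
#' g <- belief_grid(100, 100)
#' head(g$centers_d)
#' @export
belief_grid <- function(n_d = 200L, n_z = 200L) {
  if (n_d < 2 || n_z < 2) stop("grid must have at least 2 bins per axis",
                               call. = FALSE)
  n_d <- as.integer(n_d); n_z <- as.integer(n_z)
  structure(list(n_d = n_d, n_z = n_z,
                 centers_d = (seq_len(n_d) - 0.5) / n_d,
                 centers_z = (seq_len(n_z) - 0.5) / n_z),
            class = "belief_grid")
}

#' Expected cost at the response deadline
#'
#' At `t = D` no action can be taken; the trial terminates as a stop
#' response, which is correct on a stop trial and an omission error
#' otherwise, after paying the full delay cost: `V^D = c D + (1 - p_s)`.
#'
#' @param p_s Posterior stop-trial probability (vectorized).
#' @param params A [task_params()] object.
#' @return Expected cost.
#' @examples
#' terminal_value(0.25, task_params())   # 0.002*50 + 0.75 = 0.85
#' @export
terminal_value <- function(p_s, params) {
  stopifnot(inherits(params, "task_params"))
  if (any(p_s < 0 | p_s > 1)) stop("'p_s' must lie in [0, 1]", call. = FALSE)
  params$c * params$D + (1 - p_s)
}

#' Expected cost of responding now (the Go Q-factor)
#'
#' `Q_g = c t + c_s p_s + (1 - p_s) min(p_d, 1 - p_d)`: delay cost paid so
#' far, the stop-error penalty if this is a stop trial, and the chance of a
#' discrimination error when it is not (the observer responds on the more
#' probable side).
#'
#' @param p_d,p_s Posterior beliefs (vectorized, equal length or scalar).
#' @param t Current time step.
#' @param params A [task_params()] object.
#' @return Expected cost of the Go action.
#' @examples
#' q_go(0.5, 0.25, 10, task_params())   # 0.495 with the default costs
#' @export
q_go <- function(p_d, p_s, t, params) {
  stopifnot(inherits(params, "task_params"))
  if (any(p_d < 0 | p_d > 1) || any(p_s < 0 | p_s > 1))
    stop("beliefs must lie in [0, 1]", call. = FALSE)
  if (any(t < 0 | t > params$D)) stop("'t' must be in [0, D]", call. = FALSE)
  params$c * t + params$c_s * p_s + (1 - p_s) * pmin(p_d, 1 - p_d)
}

#' Predictive distribution of the next observation pair
#'
#' One-step-ahead probabilities of the four `(x, y)` outcomes given the
#' current belief, factorized as `p(x | p_d) * p(y | p_z, t)`; the `y`
#' marginal folds in the onset hazard at the next step.
#'
#' @param p_d,p_z Current beliefs (scalars).
#' @param t Current time step; the predicted observation arrives at `t + 1`.
#' @param params A [task_params()] object.
#' @return A 2 x 2 matrix of probabilities, rows indexed by `x` in \{0,1\},
#'   columns by `y` in \{0,1\}; entries sum to 1.
#' @examples
#' predictive_obs_dist(0.5, 0, 0, task_params())
#' @export
predictive_obs_dist <- function(p_d, p_z, t, params) {
  stopifnot(inherits(params, "task_params"))
  if (p_d < 0 || p_d > 1 || p_z < 0 || p_z > 1)
    stop("beliefs must lie in [0, 1]", call. = FALSE)
  px1 <- p_d * params$q_d + (1 - p_d) * (1 - params$q_d)
  h1 <- hazard(t + 1, params$r, params$q)
  pri <- p_z + (1 - p_z) * h1
  py1 <- pri * params$q_s + (1 - p_z) * (1 - h1) * (1 - params$q_s)
  m <- outer(c(1 - px1, px1), c(1 - py1, py1))
  dimnames(m) <- list(x = c("0", "1"), y = c("0", "1"))
  m
}

## Linear interpolation weights of target points onto grid centers.
## Returns an n_targets x n_centers matrix with rows summing to 1; targets
## are clamped into [first, last] center.  method "nearest" collapses each
## row onto the closer center.
interp_weights <- function(targets, centers, method = "bilinear") {
  n <- length(centers)
  t <- pmin(pmax(targets, centers[1L]), centers[n])
  k <- findInterval(t, centers, all.inside = TRUE)
  w <- (t - centers[k]) / (centers[k + 1L] - centers[k])
  if (method == "nearest") w <- round(w)
  W <- matrix(0, length(t), n)
  W[cbind(seq_along(t), k)] <- 1 - w
  W[cbind(seq_along(t), k + 1L)] <- W[cbind(seq_along(t), k + 1L)] + w
  W
}

#' Expected value of the next-step value function
#'
#' Averages `V^{t+1}` over the four possible next observation pairs: each
#' outcome's Bayes-updated belief is located on the grid (bilinear
#' interpolation by default) and weighted by its predictive probability.
#'
#' @param p_d,p_z Current beliefs (scalars).
#' @param t Current time step (the value table is for step `t + 1`).
#' @param next_value Matrix of `V^{t+1}` over the grid
#'   (`n_d` rows x `n_z` columns).
#' @param params A [task_params()] object.
#' @param grid A [belief_grid()].
#' @param interp `"bilinear"` (default) or `"nearest"`.
#' @return Scalar expected cost.
#' @export
expected_next_value <- function(p_d, p_z, t, next_value, params, grid,
                                interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(inherits(params, "task_params"), inherits(grid, "belief_grid"))
  if (p_d < 0 || p_d > 1 || p_z < 0 || p_z > 1)
    stop("beliefs must lie in [0, 1]", call. = FALSE)
  if (!all(dim(next_value) == c(grid$n_d, grid$n_z)))
    stop("'next_value' does not match the grid", call. = FALSE)
  pr <- predictive_obs_dist(p_d, p_z, t, params)
  ev <- 0
  for (x in 0:1) {
    pd1 <- update_pd(p_d, x, params$q_d)
    wd <- interp_weights(pd1, grid$centers_d, interp)
    for (y in 0:1) {
      pz1 <- update_pz(p_z, y, t + 1, params)
      wz <- interp_weights(pz1, grid$centers_z, interp)
      ev <- ev + pr[x + 1L, y + 1L] * drop(wd %*% next_value %*% t(wz))
    }
  }
  ev
}

#' Solve the stop-signal belief MDP by backward induction
#'
#' Computes value tables and Go/Wait Q-factors on the belief grid for every
#' time step, starting from the closed-form terminal value at the deadline
#' and recursing backward.  The Go region at step `t` is the set of cells
#' where `Q_g < Q_w` (exact ties wait, preserving the option to respond
#' later).
#'
#' @param params A [task_params()] object.
#' @param grid A [belief_grid()]; the reference resolution is 200 x 200.
#' @param interp Interpolation of `V^{t+1}` at updated beliefs:
#'   `"bilinear"` (default) or `"nearest"`.
#' @param deadline_ps Belief used in the wait branch at `t = D - 1`:
#'   `"carried"` evaluates `p_s` at the current step, `"advanced"` advances
#'   `p_z` through the onset hazard and evaluates `p_s` at step `D`.  The
#'   two are algebraically identical (the stop-trial posterior is a
#'   martingale); both are kept for transparency.
#' @return An object of class `"stop_policy"`: a list with `value`
#'   (length-`D` list of matrices; entry `D` is the terminal value),
#'   `q_go_table`, `q_wait_table`, `go_map` (length `D - 1` lists), plus
#'   `params`, `grid`, `interp`.
#' @examples
#' pol <- solve_policy(task_params(D = 10), belief_grid(25, 25))
#' go_region_area(pol, 9) >= go_region_area(pol, 1)
#' @export
solve_policy <- function(params, grid = belief_grid(),
                         interp = c("bilinear", "nearest"),
                         deadline_ps = c("carried", "advanced")) {
  interp <- match.arg(interp)
  deadline_ps <- match.arg(deadline_ps)
  stopifnot(inherits(params, "task_params"), inherits(grid, "belief_grid"))
  D <- params$D
  pd <- grid$centers_d; pz <- grid$centers_z
  n_d <- grid$n_d; n_z <- grid$n_z
  m_err <- pmin(pd, 1 - pd)

  value <- vector("list", D)
  qg_t <- vector("list", D - 1L)
  qw_t <- vector("list", D - 1L)
  go <- vector("list", D - 1L)

  ps_row <- function(t) prob_stop_trial(pz, t, params$r, params$q)
  value[[D]] <- matrix(terminal_value(ps_row(D), params),
                       n_d, n_z, byrow = TRUE)

  for (t in seq(D - 1L, 1L)) {
    ps_t <- ps_row(t)
    Qg <- params$c * t +
      matrix(params$c_s * ps_t, n_d, n_z, byrow = TRUE) +
      outer(m_err, 1 - ps_t)
    if (t == D - 1L) {
      ps_dl <- if (deadline_ps == "carried") {
        ps_t
      } else {
        h1 <- hazard(D, params$r, params$q)
        prob_stop_trial(pz + (1 - pz) * h1, D, params$r, params$q)
      }
      Qw <- matrix(params$c * D + 1 - ps_dl, n_d, n_z, byrow = TRUE)
    } else {
      Vn <- value[[t + 1L]]
      ## belief transitions are separable in (x, y); interpolate per axis
      h1 <- hazard(t + 1L, params$r, params$q)
      pri <- pz + (1 - pz) * h1
      px1 <- pd * params$q_d + (1 - pd) * (1 - params$q_d)
      py1 <- pri * params$q_s + (1 - pz) * (1 - h1) * (1 - params$q_s)
      Vx <- lapply(0:1, function(x) {
        interp_weights(update_pd(pd, x, params$q_d), pd, interp) %*% Vn
      })
      Qw <- matrix(0, n_d, n_z)
      for (y in 0:1) {
        Wz <- interp_weights(update_pz(pz, y, t + 1L, params), pz, interp)
        py <- if (y == 1) py1 else 1 - py1
        for (x in 0:1) {
          px <- if (x == 1) px1 else 1 - px1
          Qw <- Qw + (px %o% py) * (Vx[[x + 1L]] %*% t(Wz))
        }
      }
    }
    value[[t]] <- pmin(Qg, Qw)
    qg_t[[t]] <- Qg
    qw_t[[t]] <- Qw
    go[[t]] <- Qg < Qw
  }

  structure(list(value = value, q_go_table = qg_t, q_wait_table = qw_t,
                 go_map = go, params = params, grid = grid, interp = interp),
            class = "stop_policy")
}

## nearest grid cell of a belief coordinate
belief_cell <- function(p, n) pmin(pmax(floor(p * n) + 1L, 1L), n)

#' Optimal action at a belief state
#'
#' Looks up the Go/Wait label of the grid cell containing the belief at the
#' given step.  At `t = D` no action exists (the trial terminates).
#'
#' @param policy A [solve_policy()] result.
#' @param p_d,p_z Belief coordinates.
#' @param t Time step in `1 .. D - 1`.
#' @return `"go"` or `"wait"`.
#' @examples
#' pol <- solve_policy(task_params(D = 8), belief_grid(25, 25))
#' optimal_action(pol, 0.99, 0.0, 4)
#' @export
optimal_action <- function(policy, p_d, p_z, t) {
  stopifnot(inherits(policy, "stop_policy"))
  D <- policy$params$D
  if (t < 1 || t > D - 1) stop("'t' must be in [1, D-1]", call. = FALSE)
  if (p_d < 0 || p_d > 1 || p_z < 0 || p_z > 1)
    stop("beliefs must lie in [0, 1]", call. = FALSE)
  i <- belief_cell(p_d, policy$grid$n_d)
  j <- belief_cell(p_z, policy$grid$n_z)
  if (policy$go_map[[t]][i, j]) "go" else "wait"
}

#' Fraction of belief space where the optimal action is Go
#'
#' @param policy A [solve_policy()] result.
#' @param t Time step in `1 .. D - 1`.
#' @return Fraction of grid cells labelled Go at step `t`.
#' @export
go_region_area <- function(policy, t) {
  stopifnot(inherits(policy, "stop_policy"))
  if (any(t < 1 | t > policy$params$D - 1))
    stop("'t' must be in [1, D-1]", call. = FALSE)
  vapply(t, function(tt) mean(policy$go_map[[tt]]), numeric(1))
}

#' @export
print.stop_policy <- function(x, ...) {
  D <- x$params$D
  cat(sprintf("Optimal stop-signal policy (D = %d steps, %d x %d belief grid, %s interpolation)\n",
              D, x$grid$n_d, x$grid$n_z, x$interp))
  cat(sprintf("  q_d = %.3g, q_s = %.3g, r = %.3g, q = %.4g, c = %.4g, c_s = %.3g\n",
              x$params$q_d, x$params$q_s, x$params$r, x$params$q,
              x$params$c, x$params$c_s))
  a <- go_region_area(x, c(1L, as.integer(ceiling((D - 1) / 2)), D - 1L))
  cat(sprintf("  Go-region area: %.3f (t = 1) -> %.3f (mid) -> %.3f (t = D-1)\n",
              a[1], a[2], a[3]))
  invisible(x)
}

#' @export
summary.stop_policy <- function(object, ...) {
  D <- object$params$D
  t <- seq_len(D - 1L)
  out <- data.frame(t = t, go_area = go_region_area(object, t))
  class(out) <- c("summary.stop_policy", "data.frame")
  out
}

#' @export
print.summary.stop_policy <- function(x, ...) {
  cat("Go-region area by time step\n")
  print.data.frame(utils::head(x, 5))
  cat("...\n")
  print.data.frame(utils::tail(x, 5))
  invisible(x)
}

#' Plot a Go/Wait policy map
#'
#' Displays the Go (light) and Wait (dark) partition of the belief grid at
#' one or more time steps.
#'
#' @param x A [solve_policy()] result.
#' @param t Time steps to display (defaults to four steps spanning the trial).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.stop_policy <- function(x, t = NULL, ...) {
  D <- x$params$D
  if (is.null(t))
    t <- unique(pmax(1L, pmin(D - 1L, round(c(0.2, 0.5, 0.8, 1) * (D - 1)))))
  old <- graphics::par(mfrow = c(1, length(t)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (tt in t) {
    graphics::image(x$grid$centers_d, x$grid$centers_z,
                    x$go_map[[tt]] * 1,
                    col = grDevices::gray(c(0.15, 0.95)), zlim = c(0, 1),
                    xlab = expression(p[d]), ylab = expression(p[z]),
                    main = sprintf("t = %d", tt), ...)
  }
  invisible(x)
}

#' Save / load a solved policy
#'
#' Serializes a `stop_policy` together with its parameters, grid and a
#' format version so long simulation runs can reuse solved policies.
#'
#' @param policy A [solve_policy()] result.
#' @param path File path.
#' @return `write_policy` returns `path` invisibly; `read_policy` returns
#'   the `stop_policy`.
#' @export
write_policy <- function(policy, path) {
  stopifnot(inherits(policy, "stop_policy"))
  saveRDS(list(format = "stopsignal-policy", version = 1L, policy = policy),
          path)
  invisible(path)
}

#' @rdname write_policy
#' @export
read_policy <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "stopsignal-policy"))
    stop("not a stopsignal policy file", call. = FALSE)
  obj$policy
}
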