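## Behavioral measures computed from trial records: RT summaries, error
## rates, per-SSD inhibition functions, and smoothing-spline SSRT
## estimates.  All condition comparisons downstream aggregate per-subject
## summaries; trials are never pooled across subjects.

subset_trials <- function(trials, subject = NULL, condition = NULL) {
  if (!is.null(subject)) trials <- trials[trials$subject_id == subject, ]
  if (!is.null(condition)) trials <- trials[trials$condition == condition, ]
  trials
}

#' Summarize one subject-condition block of trials
#'
#' Go RT statistics are computed over responded go trials; the
#' discrimination error rate is wrong-side responses over go trials, the
#' omission rate no-response go trials over go trials, and the stop error
#' rate responded stop trials over stop trials.  Fields whose denominator
#' is empty are `NA` (with a warning for an empty stop subset).
#'
#' @param trials Trial-record data frame.
#' @param subject,condition Optional filters; by default all rows are used.
#' @param rt_policy `"all"` uses every responded go trial for the RT
#'   summaries (default); `"correct"` restricts to correct-side responses.
#' @return A one-row data frame of class `"condition_summary"` with
#'   columns `subject_id`, `condition`, `n_go`, `n_stop`, `mean_go_rt_ms`,
#'   `median_go_rt_ms`, `discrimination_error_rate`, `omission_error_rate`,
#'   `stop_error_rate`.
#' @export
summarize_condition <- function(trials, subject = NULL, condition = NULL,
                                rt_policy = c("all", "correct")) {
  rt_policy <- match.arg(rt_policy)
  trials <- subset_trials(trials, subject, condition)
  go <- trials[trials$trial_type == "go", ]
  stop_t <- trials[trials$trial_type == "stop", ]
  if (nrow(go) == 0) stop("no go trials in the selection", call. = FALSE)
  resp_go <- go[go$response != "none", ]
  rt_pool <- if (rt_policy == "correct")
    resp_go$rt_ms[resp_go$outcome == "go_correct"] else resp_go$rt_ms
  if (nrow(stop_t) == 0)
    warning("no stop trials in the selection; stop fields are NA",
            call. = FALSE)
  out <- data.frame(
    subject_id = if (is.null(subject)) trials$subject_id[1] else subject,
    condition = if (is.null(condition)) trials$condition[1] else condition,
    n_go = nrow(go),
    n_stop = nrow(stop_t),
    mean_go_rt_ms = if (length(rt_pool)) mean(rt_pool) else NA_real_,
    median_go_rt_ms = if (length(rt_pool)) stats::median(rt_pool) else NA_real_,
    discrimination_error_rate =
      sum(go$outcome == "discrimination_error") / nrow(go),
    omission_error_rate = sum(go$outcome == "omission_error") / nrow(go),
    stop_error_rate = if (nrow(stop_t))
      sum(stop_t$outcome == "stop_error") / nrow(stop_t) else NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("condition_summary", "data.frame")
  out
}

#' Stop-error rate as a function of SSD (the inhibition function)
#'
#' @param trials Trial-record data frame.
#' @param subject,condition Optional filters.
#' @return Data frame with columns `ssd_ms`, `se_rate`, `n` (stop-trial
#'   count), one row per SSD that has at least one stop trial, ordered by
#'   SSD.
#' @export
inhibition_function <- function(trials, subject = NULL, condition = NULL) {
  trials <- subset_trials(trials, subject, condition)
  stop_t <- trials[trials$trial_type == "stop", ]
  if (nrow(stop_t) == 0) stop("no stop trials in the selection", call. = FALSE)
  ssd <- sort(unique(stop_t$ssd_ms))
  out <- do.call(rbind, lapply(ssd, function(s) {
    sub <- stop_t[stop_t$ssd_ms == s, ]
    data.frame(ssd_ms = s,
               se_rate = mean(sub$outcome == "stop_error"),
               n = nrow(sub))
  }))
  rownames(out) <- NULL
  out
}

## smooth.spline's smoothing-parameter search reports dead-end candidates
## straight to the message stream; divert it (the chosen fit is unaffected)
quiet_fit <- function(expr) {
  sink_file <- file(tempfile(), open = "wt")
  sink(sink_file, type = "message")
  on.exit({ sink(type = "message"); close(sink_file) })
  suppressWarnings(expr)
}

## Fit the inhibition curve on a fine SSD grid, clipped to [0, 1].
## >= 5 points: cubic smoothing spline, leave-one-out smoothing;
## 4 points: spline with fixed smoothing; 3 points: linear interpolation.
fit_inhibition_curve <- function(points, smoothing = NULL) {
  x <- points$ssd_ms; y <- points$se_rate; w <- points$n
  grid <- seq(min(x), max(x), length.out = 512)
  n <- length(x)
  fitted <- if (n >= 4) {
    fit <- quiet_fit(
      if (!is.null(smoothing))
        stats::smooth.spline(x, y, w = w, spar = smoothing)
      else if (n >= 5)
        tryCatch(stats::smooth.spline(x, y, w = w, cv = TRUE),
                 error = function(e) stats::smooth.spline(x, y, w = w,
                                                          spar = 0.6))
      else
        stats::smooth.spline(x, y, w = w, spar = 0.6))
    stats::predict(fit, grid)$y
  } else {
    stats::approx(x, y, xout = grid)$y
  }
  data.frame(ssd_ms = grid, se_rate = pmin(pmax(fitted, 0), 1))
}

#' Estimate SSRT from an inhibition function
#'
#' Fits a cubic smoothing spline to the per-SSD stop-error proportions
#' (weighted by trial counts), locates the smallest SSD at which the
#' fitted curve crosses a stop-error rate of 0.5 from below (linear
#' interpolation between evaluation points), and returns
#' `SSRT = median go RT - SSD50`.  If the fitted curve starts above 0.5,
#' `SSD50` is taken at the lower edge of the SSD support and flagged; if
#' it never reaches 0.5, the estimate is `NA` and flagged rather than
#' extrapolated.
#'
#' @param points Inhibition points as returned by [inhibition_function()]
#'   (columns `ssd_ms`, `se_rate`, `n`); at least 3 distinct SSDs.
#' @param median_go_rt_ms The subject-condition median go RT.
#' @param smoothing Optional fixed smoothing parameter (`spar` of
#'   [stats::smooth.spline()]); by default chosen by leave-one-out
#'   cross-validation when there are at least 5 points.
#' @return A list with `ssrt_ms`, `ssd50_ms`, and `flag` (`"ok"`,
#'   `"starts_above"`, or `"no_crossing"`).
#' @examples
#' pts <- data.frame(ssd_ms = c(100, 200, 300, 400, 500),
#'                   se_rate = c(0.1, 0.3, 0.5, 0.7, 0.9),
#'                   n = rep(20, 5))
#' estimate_ssrt(pts, median_go_rt_ms = 500)   # SSD50 = 300, SSRT = 200
#' @export
estimate_ssrt <- function(points, median_go_rt_ms, smoothing = NULL) {
  if (!all(c("ssd_ms", "se_rate", "n") %in% names(points)))
    stop("'points' needs columns ssd_ms, se_rate, n", call. = FALSE)
  if (length(unique(points$ssd_ms)) < 3)
    stop("need at least 3 distinct SSD points", call. = FALSE)
  if (is.na(median_go_rt_ms))
    stop("'median_go_rt_ms' must be defined", call. = FALSE)
  points <- points[order(points$ssd_ms), ]
  curve <- fit_inhibition_curve(points, smoothing)
  f <- curve$se_rate; g <- curve$ssd_ms
  if (f[1] >= 0.5) {
    ssd50 <- g[1]
    flag <- "starts_above"
  } else {
    above <- which(f >= 0.5)
    if (!length(above)) {
      return(list(ssrt_ms = NA_real_, ssd50_ms = NA_real_,
                  flag = "no_crossing"))
    }
    k <- above[1]
    ssd50 <- g[k - 1] + (0.5 - f[k - 1]) / (f[k] - f[k - 1]) *
      (g[k] - g[k - 1])
    flag <- "ok"
  }
  list(ssrt_ms = median_go_rt_ms - ssd50, ssd50_ms = ssd50, flag = flag)
}

#' Per-subject, per-condition summary of a whole cohort
#'
#' Applies [summarize_condition()] and [estimate_ssrt()] to every
#' subject-condition block.  SSRT is `NA` (never fabricated) for blocks
#' whose inhibition curve has no 0.5 crossing or too few SSD points.
#'
#' @param trials Trial-record data frame.
#' @param rt_policy Passed to [summarize_condition()].
#' @param smoothing Passed to [estimate_ssrt()].
#' @return A data frame of class `"cohort_summary"`, one row per
#'   subject-condition, with the summary columns plus `ssrt_ms` and
#'   `ssrt_flag`.
#' @export
summarize_cohort <- function(trials, rt_policy = "all", smoothing = NULL) {
  blocks <- unique(trials[, c("subject_id", "condition")])
  blocks <- blocks[order(blocks$subject_id, blocks$condition), ]
  rows <- lapply(seq_len(nrow(blocks)), function(i) {
    sj <- blocks$subject_id[i]; cd <- blocks$condition[i]
    s <- suppressWarnings(
      summarize_condition(trials, sj, cd, rt_policy = rt_policy))
    ssrt <- NA_real_; flag <- "too_few_points"
    pts <- tryCatch(inhibition_function(trials, sj, cd),
                    error = function(e) NULL)
    if (!is.null(pts) && length(unique(pts$ssd_ms)) >= 3 &&
        !is.na(s$median_go_rt_ms)) {
      est <- estimate_ssrt(pts, s$median_go_rt_ms, smoothing)
      ssrt <- est$ssrt_ms; flag <- est$flag
    }
    s$ssrt_ms <- ssrt
    s$ssrt_flag <- flag
    s
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: %d subjects x %d conditions\n",
              length(unique(x$subject_id)), length(unique(x$condition))))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Condition means of a cohort summary
#'
#' Averages each behavioral measure over subjects within condition
#' (rows with undefined values are dropped per measure).
#'
#' @param summaries A [summarize_cohort()] result.
#' @param conditions Optional ordering of condition labels.
#' @return Data frame of per-condition means.
#' @export
condition_means <- function(summaries, conditions = NULL) {
  if (is.null(conditions)) conditions <- unique(summaries$condition)
  measures <- c("mean_go_rt_ms", "median_go_rt_ms",
                "discrimination_error_rate", "omission_error_rate",
                "stop_error_rate", "ssrt_ms")
  out <- do.call(rbind, lapply(conditions, function(cd) {
    sub <- summaries[summaries$condition == cd, ]
    vals <- vapply(measures, function(m) mean(sub[[m]], na.rm = TRUE),
                   numeric(1))
    cbind(data.frame(condition = cd, n_subjects = nrow(sub)),
          as.data.frame(as.list(vals)))
  }))
  rownames(out) <- NULL
  out
}
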