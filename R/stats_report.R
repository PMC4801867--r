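## Condition-comparison statistics over per-subject summaries: one-sided
## paired t-tests, with the Wilcoxon signed-rank test alongside as the
## distribution-free check.  No multiple-testing correction is applied
## (the report notes this).

#' One-sided paired t-test
#'
#' Tests the mean of the per-subject differences `a - b` against zero in
#' the stated direction.  Zero-variance differences cannot support a t
#' statistic and are flagged degenerate: all-zero differences report
#' `t = 0`, `p = 0.5`; constant nonzero differences report an infinite t.
#'
#' @param a,b Paired per-subject values (equal length >= 2).
#' @param alternative `"greater"` tests mean(a - b) > 0, `"less"` the
#'   reverse.
#' @return List with `t`, `p`, `n`, `degenerate`.
#' @examples
#' paired_t_one_sided(c(3, 1, 4, 2, 5), c(1, 2, 1, 2, 4), "greater")
#' @export
paired_t_one_sided <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b) || length(a) < 2)
    stop("'a' and 'b' must be paired vectors of length >= 2", call. = FALSE)
  keep <- !(is.na(a) | is.na(b))
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2) stop("fewer than 2 complete pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, p = 0.5, n = n, degenerate = TRUE))
    t <- sign(mean(d)) * Inf
    p <- if ((alternative == "greater") == (mean(d) > 0)) 0 else 1
    return(list(t = t, p = p, n = n, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, paired = TRUE, alternative = alternative)
  list(t = unname(ht$statistic), p = ht$p.value, n = n, degenerate = FALSE)
}

#' One-sided Wilcoxon signed-rank test
#'
#' Paired signed-rank test on `a - b`; zero differences are dropped
#' (Wilcoxon's original policy).  The null distribution is exact for up to
#' 15 nonzero untied differences, and a continuity-corrected normal
#' approximation above (or whenever ties make the exact distribution
#' unavailable).
#'
#' @inheritParams paired_t_one_sided
#' @return List with `V` (signed-rank statistic), `p`, `n` (nonzero
#'   pairs), `degenerate`.
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1), "greater")$p   # 1/8 exact
#' @export
wilcoxon_signed_rank <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b) || length(a) < 2)
    stop("'a' and 'b' must be paired vectors of length >= 2", call. = FALSE)
  keep <- !(is.na(a) | is.na(b))
  a <- a[keep]; b <- b[keep]
  d <- a - b
  nz <- d != 0
  n <- sum(nz)
  if (n == 0) return(list(V = NA_real_, p = NA_real_, n = 0L,
                          degenerate = TRUE))
  ht <- suppressWarnings(
    stats::wilcox.test(d[nz], alternative = alternative,
                       exact = n <= 15, correct = TRUE))
  list(V = unname(ht$statistic), p = ht$p.value, n = n, degenerate = FALSE)
}

default_directions <- function() {
  ## direction of the planned test for harder (a) vs easier (b) condition:
  ## RTs, error rates and SSRT are expected larger in the harder condition,
  ## the stop-error rate smaller.
  c(mean_go_rt_ms = "greater", median_go_rt_ms = "greater",
    discrimination_error_rate = "greater", omission_error_rate = "greater",
    stop_error_rate = "less", ssrt_ms = "greater")
}

#' Pairwise condition comparisons over per-subject summaries
#'
#' Runs the one-sided paired t-test and the Wilcoxon signed-rank test for
#' every planned (measure, condition pair), pairing values by subject and
#' dropping subjects with an undefined value pairwise (count logged in the
#' output).  The default plan compares every ordered pair of the supplied
#' condition ordering (hardest first), testing for larger RTs, error
#' rates and SSRT in the harder condition and a smaller stop-error rate.
#'
#' @param summaries A [summarize_cohort()] result.
#' @param conditions Condition labels ordered from hardest to easiest go
#'   discrimination; default: order of appearance.
#' @param plan Optional data frame with columns `cond_a`, `cond_b`
#'   overriding the all-ordered-pairs default.
#' @param measures Measures to test; default the six standard ones.
#' @param directions Named character vector mapping measures to
#'   `"greater"`/`"less"` for the test on (harder - easier).
#' @return A data frame of class `"comparison_report"`, one row per
#'   (measure, pair): `t`, `p_t`, `V`, `p_wilcoxon`, `n`, `n_dropped`,
#'   `degenerate`.
#' @export
comparison_report <- function(summaries, conditions = NULL, plan = NULL,
                              measures = names(default_directions()),
                              directions = default_directions()) {
  if (is.null(conditions)) conditions <- unique(summaries$condition)
  if (is.null(plan)) {
    idx <- utils::combn(seq_along(conditions), 2)
    plan <- data.frame(cond_a = conditions[idx[1, ]],
                       cond_b = conditions[idx[2, ]],
                       stringsAsFactors = FALSE)
  }
  subjects <- sort(unique(summaries$subject_id))
  if (length(subjects) < 2) stop("need at least 2 subjects", call. = FALSE)
  pick <- function(cond, measure) {
    sub <- summaries[summaries$condition == cond, ]
    sub[[measure]][match(subjects, sub$subject_id)]
  }
  rows <- list()
  for (m in measures) {
    dir <- directions[[m]]
    if (is.null(dir)) stop(sprintf("no direction given for measure '%s'", m),
                           call. = FALSE)
    for (i in seq_len(nrow(plan))) {
      a <- pick(plan$cond_a[i], m)
      b <- pick(plan$cond_b[i], m)
      ok <- !(is.na(a) | is.na(b))
      if (sum(ok) < 2) stop(sprintf(
        "fewer than 2 complete pairs for %s: %s vs %s", m,
        plan$cond_a[i], plan$cond_b[i]), call. = FALSE)
      tt <- paired_t_one_sided(a[ok], b[ok], dir)
      wt <- wilcoxon_signed_rank(a[ok], b[ok], dir)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = m, cond_a = plan$cond_a[i], cond_b = plan$cond_b[i],
        direction = dir, n = tt$n, n_dropped = sum(!ok),
        t = tt$t, p_t = tt$p, V = wt$V, p_wilcoxon = wt$p,
        degenerate = tt$degenerate || wt$degenerate,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Pairwise condition comparisons (one-sided paired t and Wilcoxon)\n")
  cat("Direction is the tested alternative for (cond_a - cond_b).\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  cat("Note: p-values are reported without multiple-testing correction.\n")
  invisible(x)
}
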