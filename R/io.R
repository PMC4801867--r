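## Trial-record CSV schema and run configuration.
##
## The CSV is the lingua franca between the two trial sources (optimal
## observer and race model) and the analysis stages: columns subject_id,
## condition, trial_type (go|stop), ssd_ms (empty on go trials), response
## (left|right|none), rt_ms (empty when response is none), outcome, and an
## optional latent_d column carried by simulated data.

TRIAL_COLUMNS <- c("subject_id", "condition", "trial_type", "ssd_ms",
                   "response", "rt_ms", "outcome", "latent_d")
OUTCOME_LEVELS <- c("go_correct", "discrimination_error", "omission_error",
                    "stop_success", "stop_error")

validate_trials <- function(x, where = "trials") {
  need <- setdiff(TRIAL_COLUMNS, "latent_d")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop(sprintf("%s: missing columns: %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  bad_row <- function(cond, msg) {
    rows <- which(cond)
    if (length(rows))
      stop(sprintf("%s: %s (rows %s%s)", where, msg,
                   paste(utils::head(rows, 5), collapse = ", "),
                   if (length(rows) > 5) ", ..." else ""), call. = FALSE)
  }
  bad_row(!x$trial_type %in% c("go", "stop"), "trial_type must be go|stop")
  bad_row(!x$response %in% c("left", "right", "none"),
          "response must be left|right|none")
  bad_row(!x$outcome %in% OUTCOME_LEVELS, "unknown outcome label")
  bad_row(x$trial_type == "go" & !is.na(x$ssd_ms),
          "ssd_ms must be empty on go trials")
  bad_row(x$trial_type == "stop" & is.na(x$ssd_ms),
          "ssd_ms must be present on stop trials")
  bad_row(x$response == "none" & !is.na(x$rt_ms),
          "rt_ms must be empty when response is none")
  bad_row(x$response != "none" & is.na(x$rt_ms),
          "rt_ms must be present when a response was made")
  bad_row(!is.na(x$rt_ms) & x$rt_ms < 0, "negative rt_ms")
  if ("latent_d" %in% names(x))
    bad_row(!is.na(x$latent_d) & !x$latent_d %in% c(0, 1),
            "latent_d must be 0 or 1")
  invisible(x)
}

#' Read / write trial records as CSV
#'
#' Lossless round-trip of the trial-record schema.  `read_trials`
#' validates the header and every row contract (SSD present exactly on
#' stop trials, RT present exactly with a response, non-negative RTs,
#' known outcome labels) and reports offending row numbers.
#'
#' @param path CSV file path.
#' @param trials Trial-record data frame.
#' @return `read_trials` returns the validated data frame; `write_trials`
#'   returns `path` invisibly.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = "", colClasses = NA)
  need <- setdiff(TRIAL_COLUMNS, "latent_d")
  if (!all(need %in% names(x)))
    stop(sprintf("malformed header: expected columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  for (col in c("ssd_ms", "rt_ms"))
    if (!is.numeric(x[[col]])) x[[col]] <- suppressWarnings(
      as.numeric(x[[col]]))
  validate_trials(x, where = path)
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  cols <- intersect(TRIAL_COLUMNS, names(trials))
  utils::write.csv(trials[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

default_config <- function() {
  list(
    model = list(r = 0.25, q = 22 / 350, q_d = c(0.55, 0.62, 0.70),
                 q_s = 0.72, D = 50L, c = 0.002, c_s = 0.4),
    sim = list(dt_ms = 22, deadline_ms = 1100, ssd_mode = "empirical",
               ssd_values_ms = seq(100, 600, by = 100),
               stop_fraction = 0.25, stop_allocation = "stratified",
               n_subjects = 20L, n_trials_per_subject = 300L,
               condition_labels = NULL, non_decision_ms = 0),
    metrics = list(smoothing = NULL, rt_policy = "all"),
    root_seed = 1L
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop(sprintf("unknown config key: %s", full), call. = FALSE)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop(sprintf("config key %s must be a mapping", full), call. = FALSE)
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a structured key-value (YAML) configuration and fills every
#' unspecified field with the reference defaults: model parameters
#' `r = 0.25`, `q_s = 0.72`, `D = 50`, `c_s = 0.4`, `c = 0.002`, the
#' `q_d` grid \{0.55, 0.62, 0.70\} (one condition per value), SSDs
#' \{100, ..., 600\} ms, 1100 ms deadline and 25% stop trials.  Unknown
#' keys and out-of-range values are errors naming the key.
#'
#' @param path YAML file, or `NULL` for the full default configuration.
#' @return An object of class `"run_config"`: list with `params_by_condition`
#'   (a [task_params()] per condition), `sim` (a [sim_config()]), `metrics`
#'   options and `root_seed`.
#' @examples
#' cfg <- load_config()
#' names(cfg$params_by_condition)
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    cfg <- merge_config(cfg, user)
  }
  m <- cfg$model
  q_d <- m$q_d
  for (v in q_d)
    if (!is.numeric(v) || v < 0.5 || v > 1)
      stop("config model.q_d values must lie in [0.5, 1]", call. = FALSE)
  labels <- cfg$sim$condition_labels
  if (is.null(labels)) labels <- sprintf("qd%.2f", q_d)
  if (length(labels) != length(q_d))
    stop("config sim.condition_labels length must match model.q_d",
         call. = FALSE)
  params_by_condition <- stats::setNames(lapply(q_d, function(v)
    task_params(r = m$r, q = m$q, q_d = v, q_s = m$q_s, D = m$D,
                c = m$c, c_s = m$c_s)), labels)
  sim <- sim_config(dt_ms = cfg$sim$dt_ms, deadline_ms = cfg$sim$deadline_ms,
                    ssd_mode = cfg$sim$ssd_mode,
                    ssd_values_ms = cfg$sim$ssd_values_ms,
                    stop_fraction = cfg$sim$stop_fraction,
                    stop_allocation = cfg$sim$stop_allocation,
                    n_subjects = cfg$sim$n_subjects,
                    n_trials_per_subject = cfg$sim$n_trials_per_subject,
                    conditions = data.frame(label = labels, q_d = q_d,
                                            stringsAsFactors = FALSE),
                    non_decision_ms = cfg$sim$non_decision_ms,
                    root_seed = cfg$root_seed)
  structure(list(params_by_condition = params_by_condition, sim = sim,
                 metrics = cfg$metrics, root_seed = cfg$root_seed),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Stop-signal run configuration\n")
  cat(sprintf("  conditions : %s (q_d = %s)\n",
              paste(names(x$params_by_condition), collapse = ", "),
              paste(vapply(x$params_by_condition, `[[`, numeric(1), "q_d"),
                    collapse = ", ")))
  cat(sprintf("  design     : %d subjects x %d trials, %.0f%% stop, SSDs %s ms\n",
              x$sim$n_subjects, x$sim$n_trials_per_subject,
              100 * x$sim$stop_fraction,
              paste(range(x$sim$ssd_values_ms), collapse = "-")))
  cat(sprintf("  root seed  : %d\n", x$root_seed))
  invisible(x)
}
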