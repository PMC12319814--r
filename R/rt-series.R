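#' Construct an RT series object
#'
#' A per-run reaction-time series: one value per trial plus masks recording
#' which trials carry an observed, usable RT (`valid`) and which were filled
#' by interpolation (`interpolated`). A trial is never both.
#'
#' @param values Per-trial numbers (ms before z-scoring, z units after).
#' @param onset_s Per-trial onset times in seconds.
#' @param valid Logical mask of observed usable RTs.
#' @param interpolated Logical mask of interpolated trials.
#' @param units "ms" or "z".
#' @param run_id Run identifier.
#' @return A data frame of class `rt_series` with columns `trial`,
#'   `onset_s`, `value`, `valid`, `interpolated` and attributes `units` and
#'   `run_id`.
#' @export
rt_series <- function(values, onset_s, valid = !is.na(values),
                      interpolated = rep(FALSE, length(values)),
                      units = "ms", run_id = 1L) {
  n <- length(values)
  stopifnot(length(onset_s) == n, length(valid) == n,
            length(interpolated) == n, units %in% c("ms", "z"))
  if (any(valid & interpolated)) {
    stop("a trial cannot be both valid and interpolated")
  }
  s <- data.frame(trial = seq_len(n), onset_s = onset_s, value = values,
                  valid = valid, interpolated = interpolated)
  attr(s, "units") <- units
  attr(s, "run_id") <- run_id
  class(s) <- c("rt_series", "data.frame")
  s
}

#' Behavioral quality control for a subject
#'
#' Applies the standard retention rules: subjects are kept only if pooled
#' go-trial accuracy (correct go responses over all go trials, omissions
#' counting against) is at least 66% and the stop-success probability lies
#' between 25% and 75%.
#'
#' @param runs List of trial data frames as from [simulate_subject()].
#' @param subject_id Optional identifier carried into the report.
#' @param min_go_accuracy,stop_prob_range Retention thresholds.
#' @return A list of class `qc_report`: `subject_id`, `go_accuracy`,
#'   `stop_probability`, `retained`, `reason` ("" when retained).
#' @export
qc_subject <- function(runs, subject_id = NA_character_,
                       min_go_accuracy = 0.66,
                       stop_prob_range = c(0.25, 0.75)) {
  if (length(runs) == 0) stop("no runs supplied")
  all_trials <- do.call(rbind, lapply(runs, function(r)
    r[, c("trial_type", "responded", "correct")]))
  go <- all_trials$trial_type == "go"
  st <- all_trials$trial_type == "stop"
  if (!any(go) || !any(st)) stop("need at least one go and one stop trial")
  go_acc <- sum(go & all_trials$responded & all_trials$correct) / sum(go)
  stop_p <- sum(st & !all_trials$responded) / sum(st)
  reasons <- character(0)
  if (go_acc < min_go_accuracy) reasons <- c(reasons, "go accuracy")
  if (stop_p < stop_prob_range[1] || stop_p > stop_prob_range[2]) {
    reasons <- c(reasons, "stop probability")
  }
  structure(list(subject_id = subject_id, go_accuracy = go_acc,
                 stop_probability = stop_p,
                 retained = length(reasons) == 0,
                 reason = paste(reasons, collapse = "; ")),
            class = "qc_report")
}

#' Extract the raw RT series of a run, flagging trials to interpolate
#'
#' Usable RTs are those from go trials with RT > 150 ms, whether the
#' response was correct or not and including responses landing after the
#' response window. Stop trials (any outcome), go omissions and go RTs at or
#' below 150 ms are flagged invalid and will be filled by interpolation.
#'
#' @param run A trial data frame (one run).
#' @param min_rt_ms Validity threshold in ms (exclusive).
#' @param run_id Run identifier for the series.
#' @return An [rt_series()] in ms with `NA` at invalid trials.
#' @export
extract_rt_series <- function(run, min_rt_ms = 150, run_id = 1L) {
  stopifnot(all(c("trial_type", "onset_s", "rt_ms", "responded") %in%
                  names(run)))
  valid <- run$trial_type == "go" & run$responded &
    !is.na(run$rt_ms) & run$rt_ms > min_rt_ms
  if (!any(valid)) stop("run has no valid go RTs")
  vals <- ifelse(valid, run$rt_ms, NA_real_)
  rt_series(vals, run$onset_s, valid = valid, units = "ms", run_id = run_id)
}

#' Z-score an RT series within its run
#'
#' The mean and SD are computed over valid trials only, before any
#' interpolation, so that interpolated values (which are functions of valid
#' z-scores) cannot bias the scale. The population SD (divisor n) is the
#' default; the sample SD is available as a switch.
#'
#' @param series An [rt_series()] in ms.
#' @param sd_type "population" (divisor n, default) or "sample" (n - 1).
#' @return The series in z units; invalid entries stay `NA`. Attributes
#'   `center` and `scale` store the run mean and SD in ms.
#' @export
zscore_run <- function(series, sd_type = c("population", "sample")) {
  stopifnot(inherits(series, "rt_series"))
  sd_type <- match.arg(sd_type)
  if (attr(series, "units") != "ms") stop("series already in z units")
  x <- series$value[series$valid]
  if (length(x) < 2) stop("need at least 2 valid trials")
  m <- mean(x)
  s <- if (sd_type == "population") sqrt(mean((x - m)^2)) else stats::sd(x)
  if (!is.finite(s) || s <= 0) stop("zero RT variance: cannot z-score")
  out <- series
  out$value <- (series$value - m) / s
  attr(out, "units") <- "z"
  attr(out, "center") <- m
  attr(out, "scale") <- s
  out
}

#' Fill invalid trials by linear interpolation between valid neighbors
#'
#' Each invalid trial is filled by linear interpolation between the nearest
#' valid trials before and after it. By default interpolation runs on the
#' trial-index grid; set `grid = "time"` to interpolate over onset seconds.
#' Gaps at the run edges take the nearest valid value. Re-running on a
#' complete series changes nothing.
#'
#' @param series An [rt_series()] (typically in z units).
#' @param grid "index" (default) or "time".
#' @return A complete series with `interpolated` set on the filled trials.
#' @export
interpolate_invalid <- function(series, grid = c("index", "time")) {
  stopifnot(inherits(series, "rt_series"))
  grid <- match.arg(grid)
  if (!any(series$valid)) stop("need at least one valid trial")
  gap <- is.na(series$value)
  if (!any(gap)) return(series)
  x <- if (grid == "index") series$trial else series$onset_s
  filled <- if (sum(series$valid) == 1) {
    rep(series$value[series$valid], nrow(series))
  } else {
    stats::approx(x[series$valid], series$value[series$valid],
                  xout = x, method = "linear", rule = 2)$y
  }
  out <- series
  out$value[gap] <- filled[gap]
  out$interpolated <- out$interpolated | (gap & !series$valid)
  out
}

#' Gaussian temporal smoothing of a complete series
#'
#' Smooths values with a Gaussian kernel evaluated over real onset times
#' (`sigma = fwhm / sqrt(8 ln 2)`), renormalizing the truncated kernel at
#' the run edges so edge trials are not attenuated. `fwhm_s = 0` is the
#' identity.
#'
#' @param series An [rt_series()] with no missing values.
#' @param fwhm_s Kernel full width at half maximum in seconds (default 7.2).
#' @return The smoothed series.
#' @export
gaussian_smooth_series <- function(series, fwhm_s = 7.2) {
  stopifnot(inherits(series, "rt_series"))
  if (fwhm_s < 0) stop("fwhm_s must be >= 0")
  if (anyNA(series$value)) stop("series must be complete before smoothing")
  if (fwhm_s == 0) return(series)
  sigma <- fwhm_s / sqrt(8 * log(2))
  d <- outer(series$onset_s, series$onset_s, "-")
  w <- exp(-d^2 / (2 * sigma^2))
  out <- series
  out$value <- as.vector(w %*% series$value) / rowSums(w)
  out
}

#' Standard per-run RT-series preparation
#'
#' Convenience wrapper: extract, z-score, interpolate. Returns the complete
#' z-unit series that the three attentional models consume.
#'
#' @inheritParams extract_rt_series
#' @inheritParams zscore_run
#' @inheritParams interpolate_invalid
#' @return A complete [rt_series()] in z units.
#' @export
prepare_rt_series <- function(run, run_id = 1L, min_rt_ms = 150,
                              sd_type = "population", grid = "index") {
  s <- extract_rt_series(run, min_rt_ms = min_rt_ms, run_id = run_id)
  s <- zscore_run(s, sd_type = sd_type)
  interpolate_invalid(s, grid = grid)
}
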