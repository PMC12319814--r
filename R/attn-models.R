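#' Construct an attentional-state series
#'
#' A per-trial model value spanning all runs of a subject, with run
#' boundaries preserved. Units depend on the model: |z| for the variance
#' time course, z for the smoothed z-score, and a probability in \[0, 1\]
#' for the HMM state series.
#'
#' @param values Per-trial model values over all runs.
#' @param run Integer run index per trial.
#' @param onset_s Onset time per trial (seconds within its run).
#' @param model "vtc", "zscore" or "hmm".
#' @return A data frame of class `attention_series` with columns `trial`
#'   (global index), `run`, `onset_s`, `value`, and attribute `model`.
#' @export
attention_series <- function(values, run, onset_s,
                             model = c("vtc", "zscore", "hmm")) {
  model <- match.arg(model)
  n <- length(values)
  stopifnot(length(run) == n, length(onset_s) == n)
  if (anyNA(values)) stop("attention series must be complete")
  if (model == "vtc" && any(values < 0)) stop("VTC values must be >= 0")
  if (model == "hmm" && any(values < -1e-10 | values > 1 + 1e-10)) {
    stop("HMM state probabilities must lie in [0, 1]")
  }
  s <- data.frame(trial = seq_len(n), run = as.integer(run),
                  onset_s = onset_s, value = values)
  attr(s, "model") <- model
  class(s) <- c("attention_series", "data.frame")
  s
}

# Apply a per-run smoothing transform to a list of complete z series and
# assemble the result into one attention_series.
series_from_runs <- function(zruns, model, transform) {
  vals <- list(); runs <- list(); onsets <- list()
  for (i in seq_along(zruns)) {
    s <- zruns[[i]]
    stopifnot(inherits(s, "rt_series"))
    if (anyNA(s$value)) stop("z series must be complete (interpolate first)")
    out <- transform(s)
    vals[[i]] <- out$value
    runs[[i]] <- rep(i, nrow(s))
    onsets[[i]] <- s$onset_s
  }
  attention_series(unlist(vals), unlist(runs), unlist(onsets), model = model)
}

#' Variance time course of a subject
#'
#' Takes the absolute value of each z-scored RT — so very fast and very slow
#' trials both score high — and Gaussian-smooths the result within each run
#' (7.2 s FWHM by default). High values mark deviant, low-attention
#' responding.
#'
#' @param zruns List of complete z-unit [rt_series()], one per run.
#' @param fwhm_s Smoothing FWHM in seconds.
#' @return An [attention_series()] with model "vtc".
#' @export
compute_vtc <- function(zruns, fwhm_s = 7.2) {
  series_from_runs(zruns, "vtc", function(s) {
    s$value <- abs(s$value)
    gaussian_smooth_series(s, fwhm_s)
  })
}

#' Smoothed z-score series of a subject
#'
#' Gaussian-smooths the signed z-scored RTs within each run. High values
#' mark slow (lapse-like) responding, low values fast (impulsive-like)
#' responding.
#'
#' @inheritParams compute_vtc
#' @return An [attention_series()] with model "zscore".
#' @export
compute_zscore_model <- function(zruns, fwhm_s = 7.2) {
  series_from_runs(zruns, "zscore", function(s) {
    gaussian_smooth_series(s, fwhm_s)
  })
}

#' HMM state-probability series of a subject
#'
#' Wraps the per-trial posterior probability of the slow (longer-RT) state
#' from a fitted [fit_gaussian_hmm()] into an attentional series aligned to
#' the subject's runs. No smoothing is applied.
#'
#' @param fit An `hmm_fit` for the concatenated runs.
#' @param zruns The list of complete z-unit [rt_series()] the model was fit
#'   to (supplies run structure and onsets).
#' @return An [attention_series()] with model "hmm".
#' @export
state_probability <- function(fit, zruns) {
  stopifnot(inherits(fit, "hmm_fit"))
  n_per_run <- vapply(zruns, nrow, integer(1))
  if (sum(n_per_run) != fit$n_obs) {
    stop("run lengths do not match the fitted series")
  }
  attention_series(fit$state_prob,
                   rep(seq_along(zruns), n_per_run),
                   unlist(lapply(zruns, function(s) s$onset_s)),
                   model = "hmm")
}

#' Go-trial accuracy as a function of the model series
#'
#' Bins each subject's go trials by their attentional-series value and
#' computes per-bin correct-go accuracy, then summarizes across subjects
#' (mean and standard error per bin). With a U-shaped generator error
#' function, the z-score model shows a parabolic accuracy profile and the
#' VTC a monotonically decreasing one.
#'
#' @param subjects List of subjects, each a list with elements `series` (an
#'   [attention_series()]) and `trials` (the concatenated trial data frame,
#'   same trial order).
#' @param bin_edges Numeric vector of bin edges (left-closed, right-open;
#'   the last bin is closed).
#' @return A list with `points` (subject x bin accuracy, `NA` for empty
#'   bins, plus per-bin trial counts) and `summary` (per-bin mean accuracy,
#'   SE and number of contributing subjects).
#' @export
accuracy_by_series_bin <- function(subjects, bin_edges) {
  stopifnot(length(bin_edges) >= 2, !is.unsorted(bin_edges))
  nb <- length(bin_edges) - 1L
  rows <- list()
  for (si in seq_along(subjects)) {
    series <- subjects[[si]]$series
    trials <- subjects[[si]]$trials
    stopifnot(nrow(series) == nrow(trials))
    go <- trials$trial_type == "go"
    v <- series$value[go]
    acc <- trials$responded[go] & trials$correct[go]
    bin <- findInterval(v, bin_edges, rightmost.closed = TRUE)
    bin[bin < 1 | bin > nb] <- NA
    for (b in seq_len(nb)) {
      inb <- !is.na(bin) & bin == b
      rows[[length(rows) + 1L]] <- data.frame(
        subject = si, bin = b,
        lo = bin_edges[b], hi = bin_edges[b + 1L],
        n_trials = sum(inb),
        accuracy = if (any(inb)) mean(acc[inb]) else NA_real_)
    }
  }
  points <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(seq_len(nb), function(b) {
    a <- points$accuracy[points$bin == b]
    a <- a[!is.na(a)]
    data.frame(bin = b, lo = bin_edges[b], hi = bin_edges[b + 1L],
               mean_accuracy = if (length(a)) mean(a) else NA_real_,
               se = if (length(a) > 1) stats::sd(a) / sqrt(length(a))
                    else NA_real_,
               n_subjects = length(a))
  }))
  list(points = points, summary = summ)
}
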