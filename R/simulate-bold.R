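#' Simulate parcellated BOLD runs coupled to an attentional series
#'
#' Forward model for testing the regression pipeline: each parcel's signal
#' is a baseline plus `coupling[p]` times the amplitude-modulated regressor
#' built from the supplied series (impulses at trial onsets, mean-centered
#' amplitudes, HRF convolution), plus optional leakage of the global
#' confound and white Gaussian noise. Nuisance series (6 motion parameters
#' as slow random walks and 3 tissue means) are generated alongside.
#'
#' @param trial_runs List of trial data frames (one per run), as from
#'   [simulate_subject()].
#' @param series An [attention_series()] spanning the runs (its values set
#'   the AM amplitudes), or a list of several such series for parcels that
#'   couple to different model series.
#' @param coupling Per-parcel coupling weights (ground truth): a vector
#'   when `series` is a single series, or a parcels x series matrix with
#'   one column per element of the series list.
#' @param noise_sd SD of the white noise added to each frame.
#' @param tr_s Frame interval in seconds (default 0.8).
#' @param hrf An [hrf_spec()].
#' @param baseline Baseline signal level (default 100).
#' @param confound_leakage Scalar weight of the (centered) global signal
#'   leaked into every parcel.
#' @param pad_s Seconds of acquisition after the last trial onset; at least
#'   the HRF support, so no response is truncated.
#' @param seed Integer seed.
#' @return A list of [bold_run()] objects with the generating `coupling`
#'   stored on each.
#' @export
simulate_bold <- function(trial_runs, series, coupling, noise_sd = 1,
                          tr_s = 0.8, hrf = hrf_spec("gaussian"),
                          baseline = 100, confound_leakage = 0,
                          pad_s = hrf$support_s, seed = 1L) {
  if (inherits(series, "attention_series")) series <- list(series)
  stopifnot(all(vapply(series, inherits, logical(1), "attention_series")))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  coupling <- if (is.null(dim(coupling))) matrix(coupling, ncol = 1)
              else as.matrix(coupling)
  if (ncol(coupling) != length(series)) {
    stop("coupling needs one column per series")
  }
  n_parcels <- nrow(coupling)
  if (n_parcels < 1) stop("coupling must have at least one parcel")
  set.seed(as.integer(seed))
  out <- vector("list", length(trial_runs))
  for (r in seq_along(trial_runs)) {
    n_frames <- ceiling((max(trial_runs[[r]]$onset_s) + pad_s) / tr_s) + 1L
    regs <- vapply(series, function(ser) {
      srun <- ser[ser$run == r, , drop = FALSE]
      if (nrow(srun) != nrow(trial_runs[[r]])) {
        stop("series is not aligned to the trials of run ", r)
      }
      build_am_regressor(srun, tr_s, n_frames, hrf = hrf)
    }, numeric(n_frames))
    motion <- vapply(1:6, function(j)
      cumsum(stats::rnorm(n_frames, 0, 0.02)), numeric(n_frames))
    tissue <- vapply(1:3, function(j)
      100 + as.vector(stats::filter(stats::rnorm(n_frames, 0, 0.5),
                                    0.9, method = "recursive")),
      numeric(n_frames))
    confounds <- cbind(motion, tissue)
    colnames(confounds) <- c(paste0("mot", 1:6), "wm", "csf", "global")
    glob_c <- tissue[, 3] - mean(tissue[, 3])
    signal <- baseline + coupling %*% t(regs) +
      matrix(rep(confound_leakage * glob_c, each = n_parcels),
             nrow = n_parcels) +
      matrix(stats::rnorm(n_parcels * n_frames, 0, noise_sd),
             nrow = n_parcels)
    out[[r]] <- bold_run(signal, tr_s = tr_s, confounds = confounds,
                         coupling = if (ncol(coupling) == 1) coupling[, 1]
                                    else coupling)
  }
  out
}
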