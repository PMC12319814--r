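#' Stop-Signal Task design parameters
#'
#' Describes the task structure used throughout the package: two runs of 180
#' trials, 30 stop trials per run (16.6%), a 1,000 ms response window, a
#' jittered 700-2,000 ms inter-trial interval, and an adaptive stop-signal
#' delay (SSD) staircase that starts at 50 ms and moves in 50 ms steps.
#'
#' The SSD is clipped to `[ssd_floor_ms, ssd_ceiling_ms]`. A floor of 0 ms is
#' physically forced; the 900 ms ceiling keeps the stop signal inside the
#' response window.
#'
#' @param n_runs Number of task runs.
#' @param n_trials_per_run Trials per run.
#' @param n_stop_per_run Stop trials per run; must be less than
#'   `n_trials_per_run`.
#' @param response_window_ms Response window in ms.
#' @param iti_min_ms,iti_max_ms Bounds of the uniform inter-trial-interval
#'   jitter in ms.
#' @param stim_duration_ms Nominal go-stimulus duration in ms (display only;
#'   the response window governs timing).
#' @param ssd_start_ms Initial stop-signal delay in ms.
#' @param ssd_step_ms Staircase step size in ms.
#' @param ssd_floor_ms,ssd_ceiling_ms Clipping bounds for the SSD in ms.
#'
#' @return An object of class `sst_design` (a named list).
#' @examples
#' d <- sst_design()
#' d$n_stop_per_run / d$n_trials_per_run  # 0.166
#' @export
sst_design <- function(n_runs = 2L,
                       n_trials_per_run = 180L,
                       n_stop_per_run = 30L,
                       response_window_ms = 1000,
                       iti_min_ms = 700,
                       iti_max_ms = 2000,
                       stim_duration_ms = 1000,
                       ssd_start_ms = 50,
                       ssd_step_ms = 50,
                       ssd_floor_ms = 0,
                       ssd_ceiling_ms = 900) {
  d <- list(
    n_runs = as.integer(n_runs),
    n_trials_per_run = as.integer(n_trials_per_run),
    n_stop_per_run = as.integer(n_stop_per_run),
    response_window_ms = response_window_ms,
    iti_min_ms = iti_min_ms,
    iti_max_ms = iti_max_ms,
    stim_duration_ms = stim_duration_ms,
    ssd_start_ms = ssd_start_ms,
    ssd_step_ms = ssd_step_ms,
    ssd_floor_ms = ssd_floor_ms,
    ssd_ceiling_ms = ssd_ceiling_ms
  )
  durations <- c(d$response_window_ms, d$iti_min_ms, d$iti_max_ms,
                 d$stim_duration_ms, d$ssd_start_ms, d$ssd_step_ms,
                 d$ssd_floor_ms, d$ssd_ceiling_ms)
  if (any(!is.finite(durations)) || any(durations < 0)) {
    stop("all durations must be finite and >= 0")
  }
  if (d$n_runs < 1L || d$n_trials_per_run < 1L || d$n_stop_per_run < 0L) {
    stop("counts must be positive")
  }
  if (d$n_stop_per_run >= d$n_trials_per_run) {
    stop("n_stop_per_run must be smaller than n_trials_per_run")
  }
  if (d$iti_min_ms > d$iti_max_ms) stop("iti_min_ms must be <= iti_max_ms")
  if (d$ssd_floor_ms > d$ssd_start_ms || d$ssd_start_ms > d$ssd_ceiling_ms) {
    stop("need ssd_floor_ms <= ssd_start_ms <= ssd_ceiling_ms")
  }
  structure(d, class = "sst_design")
}

#' U-shaped go-error probability as a function of reaction time
#'
#' Returns a function mapping RT (ms) to the probability of responding with
#' the wrong button on a go trial. The default is high for very fast
#' (< `fast_ms`) and very slow (> `slow_ms`) responses and low in between,
#' reproducing the characteristic speed-accuracy pattern in which most go
#' errors occur at extreme RTs.
#'
#' @param fast_ms RTs below this are error-prone (default 450 ms).
#' @param slow_ms RTs above this are error-prone (default 1200 ms).
#' @param p_extreme Error probability in the extreme regions.
#' @param p_base Baseline error probability in the middle region.
#' @return A vectorized function `rt_ms -> probability`.
#' @examples
#' f <- u_shaped_error_fn()
#' f(c(300, 700, 1400))
#' @export
u_shaped_error_fn <- function(fast_ms = 450, slow_ms = 1200,
                              p_extreme = 0.35, p_base = 0.02) {
  stopifnot(fast_ms < slow_ms, p_extreme >= 0, p_extreme <= 1,
            p_base >= 0, p_base <= 1)
  function(rt_ms) {
    ifelse(rt_ms < fast_ms | rt_ms > slow_ms, p_extreme, p_base)
  }
}

#' Generative parameters for the two-state attentional process
#'
#' The simulator assumes a hidden two-state Markov chain over attentional
#' states (0 = focused/fast, 1 = lapsing/slow). Go RTs are emitted from a
#' state-specific Gaussian, omissions occur with a state-specific
#' probability, go errors depend on RT through `error_fn`, and stop-trial
#' outcomes follow an independent-race model with a fixed stop-signal
#' reaction time (SSRT).
#'
#' @param state_means_ms Mean go RT per state, fast then slow (ms).
#' @param state_sds_ms Go RT standard deviation per state (ms); must be > 0.
#' @param stay_prob Self-transition probability per state, each in \[0, 1\].
#' @param omission_prob Per-state probability of a go omission, in \[0, 1\].
#' @param error_fn Function mapping RT (ms) to go-error probability; see
#'   [u_shaped_error_fn()].
#' @param ssrt_ms Stop-signal reaction time for the race model (ms).
#'
#' @return An object of class `attn_gen_params`.
#' @export
attn_gen_params <- function(state_means_ms = c(450, 650),
                            state_sds_ms = c(80, 140),
                            stay_prob = c(0.9, 0.85),
                            omission_prob = c(0.02, 0.10),
                            error_fn = u_shaped_error_fn(),
                            ssrt_ms = 250) {
  stopifnot(length(state_means_ms) == 2L, length(state_sds_ms) == 2L,
            length(stay_prob) == 2L, length(omission_prob) == 2L)
  if (state_means_ms[1] >= state_means_ms[2]) {
    stop("fast-state mean must be below slow-state mean")
  }
  if (any(state_sds_ms <= 0)) stop("state SDs must be > 0")
  if (any(stay_prob < 0 | stay_prob > 1) ||
      any(omission_prob < 0 | omission_prob > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (!is.function(error_fn)) stop("error_fn must be a function")
  if (ssrt_ms < 0) stop("ssrt_ms must be >= 0")
  structure(list(
    state_means_ms = state_means_ms,
    state_sds_ms = state_sds_ms,
    stay_prob = stay_prob,
    omission_prob = omission_prob,
    error_fn = error_fn,
    ssrt_ms = ssrt_ms
  ), class = "attn_gen_params")
}
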