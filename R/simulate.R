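#' Advance the stop-signal-delay staircase by one step
#'
#' Successful inhibition makes stopping harder (SSD increases by one step);
#' a failed stop makes it easier (SSD decreases). The result is clipped to
#' the design's `[ssd_floor_ms, ssd_ceiling_ms]`, so the staircase tracks
#' the delay at which inhibition succeeds on about half of stop trials.
#'
#' @param current_ssd_ms Current stop-signal delay in ms.
#' @param stop_succeeded Logical; `TRUE` if the response was inhibited.
#' @param design An [sst_design()].
#' @return The new SSD in ms.
#' @examples
#' step_ssd(50, TRUE)   # 100
#' step_ssd(50, FALSE)  # 0
#' step_ssd(0, FALSE)   # 0 (floor)
#' @export
step_ssd <- function(current_ssd_ms, stop_succeeded, design = sst_design()) {
  new <- current_ssd_ms + ifelse(stop_succeeded, design$ssd_step_ms,
                                 -design$ssd_step_ms)
  pmin(pmax(new, design$ssd_floor_ms), design$ssd_ceiling_ms)
}

# Truncated-normal draw via inverse CDF; lower bound is inclusive.
rtnorm_lower <- function(n, mean, sd, lower = 1) {
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

#' Simulate one subject's Stop-Signal-Task behavior
#'
#' Generates trial tables for every run of the design. A hidden two-state
#' Markov chain (focused vs. lapsing) advances once per trial and persists
#' across runs, as does the SSD staircase. On go trials the RT is drawn from
#' the current state's Gaussian, truncated below at 1 ms; omissions occur
#' with a state-specific probability, and response errors with probability
#' `gen$error_fn(rt)`. On stop trials an independent race decides the
#' outcome: a response is emitted iff the go finisher beats the stop process
#' (`rt < ssd + ssrt_ms`); the SSD staircase then updates.
#'
#' Stop trials are placed uniformly at random within each run, never on the
#' first trial; set `forbid_consecutive_stops = TRUE` to additionally forbid
#' back-to-back stop trials.
#'
#' @param design An [sst_design()].
#' @param gen An [attn_gen_params()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @param forbid_consecutive_stops Logical; forbid adjacent stop trials.
#'
#' @return A list with one data frame per run, columns: `index` (0-based),
#'   `trial_type` ("go"/"stop"), `onset_s`, `rt_ms` (`NA` when no response),
#'   `responded`, `correct`, `ssd_ms` (`NA` on go trials), `iti_ms`, and the
#'   generator ground truth `true_state` (0 fast, 1 slow). Attributes
#'   `design`, `gen` and `seed` record the generating configuration.
#' @examples
#' runs <- simulate_subject(sst_design(), attn_gen_params(), seed = 1)
#' table(runs[[1]]$trial_type)
#' @export
simulate_subject <- function(design = sst_design(), gen = attn_gen_params(),
                             seed = 1L, forbid_consecutive_stops = FALSE) {
  stopifnot(inherits(design, "sst_design"), inherits(gen, "attn_gen_params"))
  set.seed(as.integer(seed))

  n <- design$n_trials_per_run
  # start the chain from its stationary distribution
  leave <- 1 - gen$stay_prob
  p_slow <- if (sum(leave) > 0) leave[1] / sum(leave) else 0.5
  state <- as.integer(stats::runif(1) < p_slow)
  ssd <- design$ssd_start_ms

  runs <- vector("list", design$n_runs)
  for (r in seq_len(design$n_runs)) {
    stop_pos <- sample(2:n, design$n_stop_per_run)
    if (forbid_consecutive_stops) {
      while (any(diff(sort(stop_pos)) == 1L)) {
        stop_pos <- sample(2:n, design$n_stop_per_run)
      }
    }
    is_stop <- seq_len(n) %in% stop_pos

    iti <- stats::runif(n, design$iti_min_ms, design$iti_max_ms)
    onset <- c(0, cumsum((design$response_window_ms + iti[-n]) / 1000))

    rt <- rep(NA_real_, n)
    responded <- logical(n)
    correct <- logical(n)
    ssd_ms <- rep(NA_real_, n)
    true_state <- integer(n)

    for (i in seq_len(n)) {
      true_state[i] <- state
      k <- state + 1L
      go_rt <- rtnorm_lower(1, gen$state_means_ms[k], gen$state_sds_ms[k])
      omitted <- stats::runif(1) < gen$omission_prob[k]
      if (is_stop[i]) {
        ssd_ms[i] <- ssd
        # race: the go process only produces a response if it exists and wins
        responds <- !omitted && (go_rt < ssd + gen$ssrt_ms)
        if (responds) {
          rt[i] <- go_rt
          responded[i] <- TRUE
        }
        correct[i] <- !responds  # stop success = inhibited response
        ssd <- step_ssd(ssd, !responds, design)
      } else {
        if (!omitted) {
          rt[i] <- go_rt
          responded[i] <- TRUE
          correct[i] <- stats::runif(1) >= gen$error_fn(go_rt)
        }
      }
      # advance the hidden chain
      stay <- gen$stay_prob[k]
      if (stats::runif(1) >= stay) state <- 1L - state
    }

    runs[[r]] <- data.frame(
      index = seq_len(n) - 1L,
      trial_type = ifelse(is_stop, "stop", "go"),
      onset_s = onset,
      rt_ms = rt,
      responded = responded,
      correct = correct,
      ssd_ms = ssd_ms,
      iti_ms = iti,
      true_state = true_state,
      stringsAsFactors = FALSE
    )
  }
  attr(runs, "design") <- design
  attr(runs, "gen") <- gen
  attr(runs, "seed") <- as.integer(seed)
  runs
}

#' Simulate the SSD staircase against a stationary go-RT distribution
#'
#' Runs the adaptive staircase over a long sequence of stop trials with a
#' fixed Gaussian go-RT distribution and a fixed-SSRT race model. At
#' equilibrium the staircase settles at the delay where the go finisher wins
#' half the time, so the long-run stop-success rate converges to about 50%.
#'
#' @param n_trials Number of stop trials to simulate.
#' @param rt_mean_ms,rt_sd_ms Parameters of the stationary go-RT Gaussian.
#' @param ssrt_ms Stop-signal reaction time of the race model (ms).
#' @param design An [sst_design()] supplying the staircase start, step and
#'   bounds.
#' @param seed Integer seed.
#' @return A data frame with one row per stop trial: `ssd_ms` (delay in
#'   force on that trial) and `success` (inhibited or not).
#' @examples
#' s <- simulate_stop_staircase(2000, seed = 1)
#' mean(s$success)  # near 0.5
#' @export
simulate_stop_staircase <- function(n_trials = 10000L, rt_mean_ms = 500,
                                    rt_sd_ms = 100, ssrt_ms = 250,
                                    design = sst_design(), seed = 1L) {
  stopifnot(n_trials >= 1, rt_sd_ms > 0, ssrt_ms >= 0)
  set.seed(as.integer(seed))
  rt <- rtnorm_lower(n_trials, rt_mean_ms, rt_sd_ms)
  ssd <- numeric(n_trials)
  success <- logical(n_trials)
  cur <- design$ssd_start_ms
  for (i in seq_len(n_trials)) {
    ssd[i] <- cur
    success[i] <- !(rt[i] < cur + ssrt_ms)
    cur <- step_ssd(cur, success[i], design)
  }
  data.frame(ssd_ms = ssd, success = success)
}
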