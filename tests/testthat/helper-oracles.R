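# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately use direct loops / textbook formulas,
# not the package's vectorized code paths.

# Brute-force Gaussian kernel smoothing over onset times.
smooth_oracle <- function(values, onset_s, fwhm_s) {
  if (fwhm_s == 0) return(values)
  sigma <- fwhm_s / sqrt(8 * log(2))
  out <- numeric(length(values))
  for (i in seq_along(values)) {
    w <- numeric(length(values))
    for (j in seq_along(values)) {
      w[j] <- exp(-(onset_s[i] - onset_s[j])^2 / (2 * sigma^2))
    }
    out[i] <- sum(w * values) / sum(w)
  }
  out
}

# Direct impulse-summation oracle for the AM regressor (nearest-frame
# onset assignment, kernel sampled at the frame interval).
am_regressor_oracle <- function(values, onset_s, tr_s, n_frames, hrf,
                                t0_s = 0, center = TRUE) {
  amp <- if (center) values - mean(values) else values
  kv <- hrf_kernel(hrf, tr_s)
  idx <- round((onset_s - t0_s) / tr_s) + 1L
  reg <- numeric(n_frames)
  for (f in seq_len(n_frames)) {
    for (i in seq_along(idx)) {
      lag <- f - idx[i] + 1L
      if (idx[i] >= 1L && lag >= 1L && lag <= length(kv)) {
        reg[f] <- reg[f] + amp[i] * kv[lag]
      }
    }
  }
  reg
}

# Direct microtime boxcar-convolution oracle for one single-trial column.
trial_column_oracle <- function(onset_s, duration_s, tr_s, n_frames, hrf,
                                t0_s = 0, upsample = 16L) {
  dt <- tr_s / upsample
  ngrid <- (n_frames - 1L) * upsample + 1L
  tgrid <- t0_s + (seq_len(ngrid) - 1L) * dt
  u <- as.numeric(tgrid >= onset_s & tgrid < onset_s + max(duration_s, dt))
  kv <- hrf_kernel(hrf, dt)
  col <- numeric(n_frames)
  fidx <- seq(1L, ngrid, by = upsample)
  for (f in seq_along(fidx)) {
    g <- fidx[f]
    acc <- 0
    for (l in seq_along(kv)) {
      src <- g - l + 1L
      if (src >= 1L && src <= ngrid) acc <- acc + u[src] * kv[l]
    }
    col[f] <- acc * dt
  }
  col
}

# RTs emitted by a two-state Markov chain (generator for HMM tests,
# independent of simulate_subject).
markov_rts <- function(n, means, sds, stay, seed) {
  set.seed(seed)
  st <- integer(n)
  st[1] <- sample(0:1, 1)
  for (i in 2:n) {
    st[i] <- if (runif(1) < stay[st[i - 1] + 1]) st[i - 1] else 1L - st[i - 1]
  }
  list(x = rnorm(n, means[st + 1], sds[st + 1]), state = st)
}

# Minimal trial table for rt_series tests.
toy_trials <- function(trial_type, rt_ms, correct = !is.na(rt_ms),
                       onset_step_s = 2.5) {
  n <- length(trial_type)
  data.frame(
    index = seq_len(n) - 1L,
    trial_type = trial_type,
    onset_s = (seq_len(n) - 1) * onset_step_s,
    rt_ms = rt_ms,
    responded = !is.na(rt_ms),
    correct = correct & !is.na(rt_ms),
    ssd_ms = ifelse(trial_type == "stop", 200, NA_real_),
    stringsAsFactors = FALSE
  )
}

# Full per-subject behavioral + series pipeline, shared by end-to-end
# tests.
prepare_subject <- function(seed, design = sst_design(),
                            gen = attn_gen_params(), fwhm_s = 7.2) {
  runs <- simulate_subject(design, gen, seed = seed)
  z <- lapply(seq_along(runs), function(i)
    prepare_rt_series(runs[[i]], run_id = i))
  fit <- fit_gaussian_hmm(z, seed = seed + 1L)
  list(runs = runs, z = z, fit = fit,
       vtc = compute_vtc(z, fwhm_s),
       zscore = compute_zscore_model(z, fwhm_s),
       hmm = state_probability(fit, z))
}
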