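test_that("a default run has the designed trial composition and timing", {
  runs <- simulate_subject(seed = 7)
  expect_length(runs, 2)
  for (r in runs) {
    expect_equal(sum(r$trial_type == "stop"), 30)
    expect_equal(sum(r$trial_type == "go"), 150)
    expect_true(all(diff(r$onset_s) > 0))
    # ITI jitter bounds
    expect_true(all(r$iti_ms >= 700 & r$iti_ms <= 2000))
    iti_from_onsets <- diff(r$onset_s) * 1000 - 1000
    expect_true(all(iti_from_onsets >= 700 - 1e-9 &
                      iti_from_onsets <= 2000 + 1e-9))
    # field coherence
    expect_equal(!is.na(r$rt_ms), r$responded)
    expect_equal(!is.na(r$ssd_ms), r$trial_type == "stop")
    expect_false(r$trial_type[1] == "stop")
    expect_true(all(r$rt_ms >= 1, na.rm = TRUE))
  }
})

test_that("simulation is deterministic in the seed", {
  a <- simulate_subject(seed = 11)
  b <- simulate_subject(seed = 11)
  attr(a, "gen") <- attr(b, "gen") <- NULL  # closures compare by env
  expect_identical(a, b)
  c2 <- simulate_subject(seed = 12)
  expect_false(identical(a[[1]]$rt_ms, c2[[1]]$rt_ms))
})

test_that("the SSD staircase steps and clips as designed", {
  d <- sst_design()
  expect_equal(step_ssd(50, TRUE, d), 100)
  expect_equal(step_ssd(50, FALSE, d), 0)
  expect_equal(step_ssd(0, FALSE, d), 0)
  expect_equal(step_ssd(900, TRUE, d), 900)
  s <- simulate_stop_staircase(3000, seed = 2)
  expect_true(all(s$ssd_ms >= 0 & s$ssd_ms <= 900))
})

test_that("invalid design or generator parameters are rejected", {
  expect_error(sst_design(n_stop_per_run = 180), "smaller")
  expect_error(sst_design(iti_min_ms = 3000), "iti_min")
  expect_error(sst_design(ssd_start_ms = -5), ">= 0")
  expect_error(attn_gen_params(state_sds_ms = c(0, 100)), "SD")
  expect_error(attn_gen_params(state_means_ms = c(600, 500)), "mean")
  expect_error(attn_gen_params(stay_prob = c(1.2, 0.5)), "\\[0, 1\\]")
})

test_that("go RTs per hidden state match the generating distribution", {
  gen <- attn_gen_params(omission_prob = c(0, 0))
  design <- sst_design(n_runs = 1, n_trials_per_run = 6000,
                       n_stop_per_run = 10)
  run <- simulate_subject(design, gen, seed = 21)[[1]]
  go <- run[run$trial_type == "go" & run$responded, ]
  for (st in 0:1) {
    x <- go$rt_ms[go$true_state == st]
    k <- st + 1
    tol_mean <- 4 * gen$state_sds_ms[k] / sqrt(length(x))
    expect_lt(abs(mean(x) - gen$state_means_ms[k]), tol_mean)
    expect_lt(abs(sd(x) - gen$state_sds_ms[k]), 0.1 * gen$state_sds_ms[k])
  }
})

test_that("hidden-state dwell times are geometric with the stay probability", {
  gen <- attn_gen_params(stay_prob = c(0.9, 0.85))
  design <- sst_design(n_runs = 1, n_trials_per_run = 6000,
                       n_stop_per_run = 10)
  run <- simulate_subject(design, gen, seed = 31)[[1]]
  rl <- rle(run$true_state)
  for (st in 0:1) {
    len <- rl$lengths[rl$values == st]
    len <- len[-length(len)]  # last dwell may be censored by the run end
    p_leave <- 1 - gen$stay_prob[st + 1]
    kmax <- 12
    obs <- tabulate(pmin(len, kmax), nbins = kmax)
    probs <- c(stats::dgeom(0:(kmax - 2), p_leave),
               1 - stats::pgeom(kmax - 2, p_leave))
    ct <- suppressWarnings(chisq.test(obs, p = probs))
    expect_gt(ct$p.value, 0.01)
  }
})

test_that("simulated BOLD follows the zero and determinism contracts", {
  runs <- simulate_subject(sst_design(n_trials_per_run = 40,
                                      n_stop_per_run = 6), seed = 5)
  z <- lapply(seq_along(runs), function(i)
    prepare_rt_series(runs[[i]], run_id = i))
  zs <- compute_zscore_model(z)
  b0 <- simulate_bold(runs, zs, coupling = c(0, 0, 0), noise_sd = 0,
                      confound_leakage = 0, seed = 9)
  expect_true(all(b0[[1]]$signal == 100))
  b1 <- simulate_bold(runs, zs, coupling = c(1, -1, 0), noise_sd = 0.3,
                      seed = 9)
  b2 <- simulate_bold(runs, zs, coupling = c(1, -1, 0), noise_sd = 0.3,
                      seed = 9)
  expect_identical(b1[[1]]$signal, b2[[1]]$signal)
  expect_error(simulate_bold(runs, zs, coupling = c(1, 1), noise_sd = -1),
               "noise_sd")
  # frame grid covers every trial plus the HRF support
  last <- max(runs[[1]]$onset_s)
  expect_gte(ncol(b1[[1]]$signal) * 0.8, last + 16)
})

test_that("events and BOLD round-trip through their TSV formats", {
  dir <- withr::local_tempdir()
  runs <- simulate_subject(sst_design(n_trials_per_run = 30,
                                      n_stop_per_run = 5), seed = 3)
  p <- file.path(dir, "run1_events.tsv")
  write_sst_events(runs[[1]], p, design = sst_design())
  back <- read_sst_events(p)
  expect_equal(back$trial_type, runs[[1]]$trial_type)
  expect_equal(back$onset_s, runs[[1]]$onset_s, tolerance = 1e-5)
  expect_equal(back$rt_ms, runs[[1]]$rt_ms, tolerance = 1e-3)
  expect_equal(back$responded, runs[[1]]$responded)
  expect_equal(back$true_state, runs[[1]]$true_state)
  expect_true(file.exists(file.path(dir, "run1_events.json")))

  z <- prepare_rt_series(runs[[1]])
  zs <- compute_zscore_model(list(z))
  bold <- simulate_bold(runs[1], zs, coupling = c(0.5, -0.5),
                        noise_sd = 0.1, seed = 4)
  bp <- file.path(dir, "bold1.tsv")
  write_bold_run(bold[[1]], bp)
  rb <- read_bold_run(bp)
  expect_equal(rb$signal, bold[[1]]$signal, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(rb$coupling, c(0.5, -0.5))
  expect_equal(rb$tr_s, 0.8)
})
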