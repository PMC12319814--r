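test_that("QC applies the go-accuracy and stop-probability retention rules", {
  mk <- function(go_correct, stop_inhibited) {
    n_go <- length(go_correct); n_st <- length(stop_inhibited)
    data.frame(
      trial_type = c(rep("go", n_go), rep("stop", n_st)),
      responded = c(go_correct, !stop_inhibited),
      correct = c(go_correct, stop_inhibited)
    )
  }
  # 65% go accuracy -> excluded for accuracy
  r <- qc_subject(list(mk(rep(c(TRUE, FALSE), c(65, 35)),
                          rep(c(TRUE, FALSE), c(5, 5)))))
  expect_false(r$retained)
  expect_match(r$reason, "go accuracy")
  expect_equal(r$go_accuracy, 0.65)
  # 80% stop probability -> excluded for stop probability
  r <- qc_subject(list(mk(rep(TRUE, 90), rep(c(TRUE, FALSE), c(8, 2)))))
  expect_false(r$retained)
  expect_match(r$reason, "stop probability")
  expect_equal(r$stop_probability, 0.8)
  # clean subject retained
  r <- qc_subject(list(mk(rep(c(TRUE, FALSE), c(9, 1)),
                          rep(c(TRUE, FALSE), c(5, 5)))))
  expect_true(r$retained)
  expect_equal(r$reason, "")
  expect_error(qc_subject(list()), "no runs")
})

test_that("RT validity follows the go/RT>150ms rule, stop trials are gaps", {
  tr <- toy_trials(c("go", "go", "stop", "go", "go"),
                   c(140, 600, 500, NA, 900),
                   correct = c(TRUE, FALSE, FALSE, FALSE, TRUE))
  s <- extract_rt_series(tr)
  expect_equal(s$valid, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(s$value, c(NA, 600, NA, NA, 900))
  # incorrect go with usable RT is valid; boundary 150 is invalid
  tb <- toy_trials(c("go", "go"), c(150, 151))
  expect_equal(extract_rt_series(tb)$valid, c(FALSE, TRUE))
  expect_error(extract_rt_series(toy_trials("go", NA_real_)), "no valid")
})

test_that("z-scoring uses valid trials only with the population SD", {
  tr <- toy_trials(c("go", "go", "stop"), c(400, 600, 500))
  z <- zscore_run(extract_rt_series(tr))
  expect_equal(z$value[1:2], c(-1, 1))        # population SD = 100
  expect_true(is.na(z$value[3]))
  expect_equal(attr(z, "center"), 500)
  expect_equal(attr(z, "scale"), 100)
  # sample-SD switch
  zs <- zscore_run(extract_rt_series(tr), sd_type = "sample")
  expect_equal(zs$value[1:2], c(-1, 1) * 100 / sd(c(400, 600)))
  # valid z-values have mean 0, population SD 1
  set.seed(4)
  tr2 <- toy_trials(rep("go", 40), runif(40, 300, 900))
  z2 <- zscore_run(extract_rt_series(tr2))
  expect_equal(mean(z2$value), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z2$value^2)), 1, tolerance = 1e-12)
  expect_error(zscore_run(extract_rt_series(
    toy_trials(rep("go", 3), rep(500, 3)))), "variance")
})

test_that("linear interpolation fills gaps on the trial-index grid", {
  s <- rt_series(c(1, NA, 3), onset_s = c(0, 2, 4), units = "z")
  out <- interpolate_invalid(s)
  expect_equal(out$value, c(1, 2, 3))
  expect_equal(out$interpolated, c(FALSE, TRUE, FALSE))
  s2 <- rt_series(c(0, NA, NA, 3), onset_s = 0:3, units = "z")
  expect_equal(interpolate_invalid(s2)$value, c(0, 1, 2, 3))
  # leading/trailing gaps take the nearest valid value
  s3 <- rt_series(c(NA, 2, NA), onset_s = 0:2, units = "z")
  expect_equal(interpolate_invalid(s3)$value, c(2, 2, 2))
  # time-grid switch respects irregular onsets
  s4 <- rt_series(c(0, NA, 4), onset_s = c(0, 1, 4), units = "z")
  expect_equal(interpolate_invalid(s4, grid = "time")$value[2], 1)
  # idempotence
  once <- interpolate_invalid(s2)
  expect_identical(interpolate_invalid(once), once)
  expect_error(interpolate_invalid(
    rt_series(rep(NA_real_, 3), onset_s = 0:2, units = "z")), "valid")
})

test_that("Gaussian smoothing matches the brute-force kernel oracle", {
  set.seed(9)
  onsets <- cumsum(runif(40, 1.7, 3))
  vals <- rnorm(40)
  s <- rt_series(vals, onset_s = onsets, units = "z")
  for (fwhm in c(2, 7.2, 20)) {
    expect_equal(gaussian_smooth_series(s, fwhm)$value,
                 smooth_oracle(vals, onsets, fwhm), tolerance = 1e-10)
  }
  # identity and constant fixed points
  expect_identical(gaussian_smooth_series(s, 0), s)
  sc <- rt_series(rep(2.5, 10), onset_s = seq(0, 22.5, by = 2.5),
                  units = "z")
  expect_equal(gaussian_smooth_series(sc, 7.2)$value, rep(2.5, 10))
  # unit impulse equals the normalized kernel row
  si <- rt_series(c(0, 0, 1, 0, 0), onset_s = seq(0, 9.6, by = 2.4),
                  units = "z")
  expect_equal(gaussian_smooth_series(si, 7.2)$value,
               smooth_oracle(si$value, si$onset_s, 7.2), tolerance = 1e-12)
  expect_error(gaussian_smooth_series(s, -1), "fwhm")
})

test_that("smoothing never extends the value range", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    s <- rt_series(rnorm(n), onset_s = cumsum(runif(n, 1.7, 3)),
                   units = "z")
    out <- gaussian_smooth_series(s, runif(1, 0.5, 15))
    expect_true(all(out$value >= min(s$value) - 1e-12))
    expect_true(all(out$value <= max(s$value) + 1e-12))
  }
})

test_that("the interpolated fraction equals the invalid-trial fraction", {
  runs <- simulate_subject(seed = 13)
  for (i in seq_along(runs)) {
    s <- prepare_rt_series(runs[[i]], run_id = i)
    raw <- extract_rt_series(runs[[i]], run_id = i)
    expect_equal(mean(s$interpolated), mean(!raw$valid))
    expect_false(any(s$valid & s$interpolated))
    expect_false(anyNA(s$value))
  }
})
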