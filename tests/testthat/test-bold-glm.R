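test_that("preprocessing drops frames, shifts time zero, and normalizes", {
  sig <- matrix(rnorm(4 * 400, mean = 50), nrow = 4)
  conf <- matrix(rnorm(400 * 9), ncol = 9)
  run <- bold_run(sig, tr_s = 0.8, confounds = conf)
  # identity mode
  same <- preprocess_bold(run, n_drop_frames = 0, normalize = "none")
  expect_identical(same$signal, sig)
  # frame dropping
  out <- preprocess_bold(run, n_drop_frames = 8, normalize = "none")
  expect_equal(ncol(out$signal), 392)
  expect_equal(nrow(out$confounds), 392)
  expect_equal(out$t0_s, 8 * 0.8)
  # mean-100 scaling; a constant series is a fixed point at 100
  cst <- bold_run(matrix(7, 2, 50), tr_s = 0.8)
  expect_true(all(preprocess_bold(cst, 0, "mean100")$signal == 100))
  norm <- preprocess_bold(run, 0, "mean100")
  expect_equal(rowMeans(norm$signal), rep(100, 4))
  expect_error(preprocess_bold(run, 400), "n_drop_frames")
})

test_that("the confound model expands to exactly 21 columns", {
  n <- 60
  motion <- matrix(rnorm(n * 6), ncol = 6)
  tissue <- matrix(rnorm(n * 3), ncol = 3)
  X <- build_confound_matrix(motion, tissue)
  expect_equal(ncol(X), 21)
  expect_equal(nrow(X), n)
  # zero motion -> all 18 motion-derived columns are zero
  X0 <- build_confound_matrix(matrix(0, n, 6), tissue)
  expect_true(all(X0[, 1:18] == 0))
  expect_equal(X0[, 19:21], tissue, ignore_attr = TRUE)
  # derivative of a ramp is constant after the zero-padded first row
  ramp <- matrix(rep(2 * (1:n), 6), ncol = 6)
  Xr <- build_confound_matrix(ramp, tissue)
  expect_true(all(Xr[-1, 7:12] == 2))
  expect_true(all(Xr[1, 7:12] == 0))
  expect_error(build_confound_matrix(motion[, 1:5], tissue), "6 motion")
})

test_that("nuisance residuals are orthogonal to every confound column", {
  set.seed(12)
  n <- 120
  conf <- build_confound_matrix(matrix(rnorm(n * 6), ncol = 6),
                                matrix(rnorm(n * 3), ncol = 3))
  Y <- matrix(rnorm(5 * n), nrow = 5)
  R <- regress_nuisance(Y, conf)
  for (j in seq_len(ncol(conf))) {
    dot <- abs(sum(R[1, ] * conf[, j]))
    expect_lt(dot, 1e-8 * sqrt(sum(R[1, ]^2)) * sqrt(sum(conf[, j]^2)))
  }
  # a parcel equal to a confound column residualizes to ~0
  Y2 <- rbind(conf[, 3], Y)
  R2 <- regress_nuisance(Y2, conf)
  expect_lt(max(abs(R2[1, ])), 1e-10)
  # projection contracts energy
  expect_true(all(rowSums(R^2) <= rowSums(Y^2) + 1e-8))
  # collinear columns are tolerated with a warning
  expect_warning(regress_nuisance(Y, cbind(conf, conf[, 1])), "rank")
})

test_that("the AM regressor equals the direct convolution oracle", {
  hrf <- hrf_spec("gaussian")
  onsets <- c(0, 2.7, 5.3, 9.1, 14.4)
  vals <- c(1.2, -0.4, 0.0, 2.2, -1.6)
  ser <- data.frame(value = vals, onset_s = onsets)
  n_frames <- 40
  reg <- build_am_regressor(ser, 0.8, n_frames, hrf)
  expect_equal(reg, am_regressor_oracle(vals, onsets, 0.8, n_frames, hrf),
               tolerance = 1e-10)
  # centered all-equal amplitudes -> zero regressor
  ser0 <- data.frame(value = rep(3, 5), onset_s = onsets)
  expect_equal(build_am_regressor(ser0, 0.8, n_frames, hrf),
               rep(0, n_frames), tolerance = 1e-12)
  # one impulse of amplitude a reproduces the sampled kernel
  ser1 <- data.frame(value = 2.5, onset_s = 4)
  r1 <- build_am_regressor(ser1, 0.8, n_frames, hrf, center = FALSE)
  k <- hrf_kernel(hrf, 0.8)
  idx <- round(4 / 0.8) + 1
  expect_equal(r1[idx:(idx + length(k) - 1)], 2.5 * k, tolerance = 1e-12)
  expect_error(build_am_regressor(ser1, 0.8, 3, hrf), "beyond run end")
})

test_that("the AM GLM matches a hand-computed OLS oracle", {
  reg <- c(0, 0.2, 0.8, 1, 0.7, 0.3, 0.1, 0, -0.1, 0)
  y <- 1.5 * reg + c(0.05, -0.03, 0.02, 0.01, -0.04, 0.06, 0, -0.02,
                     0.03, -0.01)
  fit <- fit_am_glm(matrix(y, nrow = 1), reg)
  ref <- summary(lm(y ~ reg))$coefficients["reg", ]
  expect_equal(fit$beta, unname(ref["Estimate"]), tolerance = 1e-10)
  expect_equal(sqrt(fit$var), unname(ref["Std. Error"]), tolerance = 1e-10)
  expect_equal(fit$tstat, unname(ref["t value"]), tolerance = 1e-10)
  expect_equal(fit$dof, 8)
  # exact linear signal recovers the slope with ~zero residual variance
  f2 <- fit_am_glm(matrix(2 * reg, nrow = 1), reg)
  expect_equal(f2$beta, 2, tolerance = 1e-12)
  expect_lt(f2$var, 1e-20)
  expect_error(fit_am_glm(matrix(y, nrow = 1), rep(1, 10)), "variance")
})

test_that("AM-GLM betas recover the generating coupling at zero noise", {
  runs <- simulate_subject(sst_design(n_trials_per_run = 60,
                                      n_stop_per_run = 10), seed = 33)
  z <- lapply(seq_along(runs), function(i)
    prepare_rt_series(runs[[i]], run_id = i))
  zs <- compute_zscore_model(z)
  coup <- c(2, 1, 0.5, 0, -0.5, -1, -2)
  bold <- simulate_bold(runs, zs, coupling = coup, noise_sd = 0, seed = 2)
  b <- bold[[1]]
  reg <- build_am_regressor(zs[zs$run == 1, ], 0.8, ncol(b$signal))
  fit <- fit_am_glm(b$signal, reg)
  expect_equal(fit$beta, coup, tolerance = 1e-8)
  expect_gt(cor(fit$beta, coup), 0.99)
})

test_that("fixed-effects combination follows the inverse-variance closed form", {
  g <- function(beta, var) {
    data.frame(unit = seq_along(beta), beta = beta, var = var)
  }
  # equal variances -> simple mean
  fx <- combine_runs_fixed_effects(list(g(c(1, 4), c(2, 2)),
                                        g(c(3, 0), c(2, 2))))
  expect_equal(fx$beta, c(2, 2))
  expect_equal(fx$var, c(1, 1))
  # textbook two-run case
  fx2 <- combine_runs_fixed_effects(list(g(1, 1), g(3, 1)))
  expect_equal(fx2$beta, 2)
  expect_equal(fx2$var, 0.5)
  # an infinite-variance run contributes nothing
  fx3 <- combine_runs_fixed_effects(list(g(1, 0.5), g(100, Inf)))
  expect_equal(fx3$beta, 1)
  expect_equal(fx3$var, 0.5)
  # all unusable -> NA
  fx4 <- combine_runs_fixed_effects(list(g(1, NA), g(2, Inf)))
  expect_true(is.na(fx4$beta))
})

test_that("the group map matches a one-sample t oracle and caps degeneracy", {
  set.seed(14)
  B <- matrix(rnorm(5 * 3, mean = 0.4), nrow = 5)
  gm <- group_level_glm(B)
  for (u in 1:3) {
    tt <- t.test(B[, u])
    expect_equal(gm$tstat[u], unname(tt$statistic), tolerance = 1e-10)
    z_ref <- sign(tt$statistic) * qnorm(pt(abs(tt$statistic), 4,
                                           lower.tail = FALSE), lower.tail = FALSE)
    expect_equal(gm$zstat[u], unname(z_ref), tolerance = 1e-8)
  }
  # covariate adjustment with centered age and sex
  age <- c(9.1, 9.5, 10.0, 10.2, 9.8)
  sex <- c("F", "M", "F", "M", "F")
  gmc <- group_level_glm(B, covariates = data.frame(age = age, sex = sex))
  ref <- summary(lm(B[, 1] ~ I(age - mean(age)) +
                      I(sx - mean(sx)), data = list(sx = as.integer(sex == "M"))))
  expect_equal(gmc$beta[1], unname(ref$coefficients[1, 1]),
               tolerance = 1e-10)
  expect_equal(gmc$tstat[1], unname(ref$coefficients[1, 3]),
               tolerance = 1e-10)
  # degenerate unit: identical betas -> capped z with warning
  Bd <- cbind(rep(1.5, 5))
  expect_warning(gd <- group_level_glm(Bd), "capped")
  expect_equal(gd$zstat, 40)
  expect_error(group_level_glm(B[1:2, ]), "3 subjects")
})
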