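#' Per-trial regressor durations in seconds
#'
#' Single-trial designs use duration = RT for every trial. Stop trials and
#' omissions have no RT, so their duration is taken from the interpolated
#' z series mapped back to milliseconds with the run's mean and SD (the
#' `center`/`scale` attributes that [zscore_run()] stores), floored at
#' 1 ms.
#'
#' @param run Trial data frame for one run.
#' @param zrun The complete z-unit [rt_series()] of the same run.
#' @return Numeric vector of durations in seconds, one per trial.
#' @export
trial_durations_s <- function(run, zrun) {
  stopifnot(nrow(run) == nrow(zrun))
  center <- attr(zrun, "center")
  scale <- attr(zrun, "scale")
  if (is.null(center) || is.null(scale)) {
    stop("zrun must carry the run mean/SD (use zscore_run)")
  }
  ms <- ifelse(zrun$valid, run$rt_ms, zrun$value * scale + center)
  if (anyNA(ms)) stop("zrun must be complete (interpolate first)")
  pmax(ms, 1) / 1000
}

#' Single-trial (least-squares-all) design matrix
#'
#' One regressor per trial: a boxcar from the trial onset lasting the
#' trial's duration, convolved with the canonical double-gamma HRF on an
#' upsampled microtime grid and sampled at the frame times.
#'
#' @param onsets_s Trial onsets in seconds (strictly increasing, no
#'   duplicates).
#' @param durations_s Per-trial durations in seconds (see
#'   [trial_durations_s()]).
#' @param tr_s Frame interval in seconds.
#' @param n_frames Number of frames in the run.
#' @param hrf An [hrf_spec()]; canonical double gamma by default.
#' @param t0_s Time of the first frame.
#' @param upsample Microtime resolution: grid step is `tr_s / upsample`.
#' @return A frames x trials matrix.
#' @export
build_trial_design <- function(onsets_s, durations_s, tr_s, n_frames,
                               hrf = hrf_spec("double_gamma"), t0_s = 0,
                               upsample = 16L) {
  n_tr <- length(onsets_s)
  stopifnot(length(durations_s) == n_tr, n_tr >= 1)
  if (anyDuplicated(onsets_s)) stop("overlapping identical onsets")
  run_end <- t0_s + (n_frames - 1) * tr_s
  if (any(onsets_s > run_end)) stop("trial onset beyond run end")
  dt <- tr_s / upsample
  ngrid <- (n_frames - 1L) * upsample + 1L
  tgrid <- t0_s + (seq_len(ngrid) - 1L) * dt
  k <- hrf_kernel(hrf, dt)
  X <- matrix(0, n_frames, n_tr)
  frame_idx <- seq(1L, ngrid, by = upsample)
  for (j in seq_len(n_tr)) {
    u <- as.numeric(tgrid >= onsets_s[j] &
                      tgrid < onsets_s[j] + max(durations_s[j], dt))
    conv <- stats::convolve(u, rev(k), type = "open")[seq_len(ngrid)] * dt
    X[, j] <- conv[frame_idx]
  }
  X
}

#' Estimate trial-wise betas by joint least squares
#'
#' Fits all trial regressors jointly (least-squares-all) per parcel, with
#' an intercept. When the design has more columns than frames or is badly
#' conditioned, a ridge penalty on the trial columns is used instead and
#' the result is flagged.
#'
#' @param residuals Parcels x frames matrix of nuisance-cleaned BOLD.
#' @param design Frames x trials matrix from [build_trial_design()].
#' @param cond_threshold Condition-number threshold that triggers the
#'   ridge fallback.
#' @param ridge_lambda Ridge penalty; defaults to `1e-3` times the mean
#'   squared column norm of the design.
#' @return Trials x parcels matrix of class `trial_beta_matrix` with
#'   attributes `ridge` (logical) and `estimable` (per-trial flag; trials
#'   whose regressor carries no energy in the retained frames are `NA`).
#' @export
estimate_trial_betas <- function(residuals, design, cond_threshold = 1e8,
                                 ridge_lambda = NULL) {
  Y <- as.matrix(residuals)
  D <- as.matrix(design)
  n <- ncol(Y)
  stopifnot(nrow(D) == n)
  # trials whose regressor never enters the retained frames (e.g., events
  # inside dropped initial frames) are inestimable and come back NA
  estimable <- colSums(D^2) > 1e-12
  De <- D[, estimable, drop = FALSE]
  X <- cbind(1, De)
  sv <- svd(X, nu = 0, nv = 0)$d
  cond <- sv[1] / max(sv[length(sv)], .Machine$double.xmin)
  use_ridge <- n <= ncol(X) || cond > cond_threshold
  if (use_ridge) {
    warning("design is rank-limited or ill-conditioned; ridge fallback used")
    if (is.null(ridge_lambda)) ridge_lambda <- 1e-3 * mean(colSums(De^2))
    pen <- diag(c(0, rep(ridge_lambda, ncol(De))))
    coefs <- solve(crossprod(X) + pen, crossprod(X, t(Y)))
  } else {
    coefs <- qr.coef(qr(X), t(Y))
  }
  betas <- matrix(NA_real_, ncol(D), nrow(Y))
  betas[estimable, ] <- coefs[-1, , drop = FALSE]
  structure(betas, class = c("trial_beta_matrix", "matrix"),
            ridge = use_ridge, estimable = estimable)
}

#' Per-parcel correlation between go-trial betas and an attentional series
#'
#' Pearson correlation, restricted to go trials with estimable betas,
#' between a subject's trial-wise BOLD parameter estimates and their RT
#' model series. Parcels whose betas have zero variance yield `NA`.
#'
#' @param betas Trials x parcels matrix from [estimate_trial_betas()].
#' @param series An [attention_series()] aligned to the same trials.
#' @param trials Concatenated trial data frame (same order).
#' @param min_go Minimum number of go trials required.
#' @return Named numeric vector of per-parcel correlations.
#' @export
subject_rt_bold_correlation <- function(betas, series, trials,
                                        min_go = 10L) {
  B <- as.matrix(betas)
  stopifnot(nrow(B) == nrow(trials), nrow(series) == nrow(trials))
  go <- trials$trial_type == "go" & stats::complete.cases(B)
  if (sum(go) < min_go) stop("need at least ", min_go, " go trials")
  x <- series$value[go]
  if (stats::sd(x) == 0) stop("series has zero variance over go trials")
  Bg <- B[go, , drop = FALSE]
  sds <- apply(Bg, 2, stats::sd)
  r <- rep(NA_real_, ncol(Bg))
  ok <- sds > 0
  if (any(ok)) r[ok] <- as.vector(stats::cor(Bg[, ok, drop = FALSE], x))
  r
}

#' Covariate-adjusted Cohen's d of the RT-BOLD correlation per parcel
#'
#' For each parcel, regresses the per-subject correlations on an intercept
#' plus centered age and a sex indicator; Cohen's d is the intercept (the
#' covariate-adjusted mean correlation) divided by the residual standard
#' deviation. The alternative `"t_sqrt_n"` definition (intercept t over
#' sqrt(n)) is provided as a switch, as is an optional Fisher z transform
#' of the correlations before regression.
#'
#' @param r_matrix Subjects x parcels matrix of per-subject correlations.
#' @param age Numeric vector of ages (centered internally).
#' @param sex Factor or character vector of sex labels.
#' @param parcellation Optional parcellation table supplying network
#'   labels (see [synthetic_parcellation()]).
#' @param d_method "intercept_sd" (default) or "t_sqrt_n".
#' @param fisher_z Apply `atanh` to the correlations first.
#' @return A data frame of class `effect_table`: `parcel`, `network`,
#'   `cohens_d`, `mean_r`, `sd_r`, `n`.
#' @export
effect_size_table <- function(r_matrix, age = NULL, sex = NULL,
                              parcellation = NULL,
                              d_method = c("intercept_sd", "t_sqrt_n"),
                              fisher_z = FALSE) {
  d_method <- match.arg(d_method)
  R <- as.matrix(r_matrix)
  n <- nrow(R)
  if (n < 3) stop("need at least 3 subjects")
  if (fisher_z) R <- atanh(pmin(pmax(R, -1 + 1e-12), 1 - 1e-12))
  X <- matrix(1, n, 1)
  if (!is.null(age)) {
    if (length(unique(age)) > 1) {
      X <- cbind(X, age - mean(age))
    } else {
      warning("age is constant; dropped")
    }
  }
  if (!is.null(sex)) {
    sx <- as.integer(factor(sex)) - 1
    if (length(unique(sx)) > 1) {
      X <- cbind(X, sx - mean(sx))
    } else {
      warning("sex is constant; dropped")
    }
  }
  dof <- n - ncol(X)
  XtXi <- solve(crossprod(X))
  coef <- XtXi %*% crossprod(X, R)
  resid <- R - X %*% coef
  sigma <- sqrt(colSums(resid^2) / dof)
  b0 <- coef[1, ]
  d <- if (d_method == "intercept_sd") {
    ifelse(sigma > 0, b0 / sigma, 0)
  } else {
    se <- sigma * sqrt(XtXi[1, 1])
    ifelse(se > 0, (b0 / se) / sqrt(n), 0)
  }
  network <- if (!is.null(parcellation)) {
    parcellation$network[seq_len(ncol(R))]
  } else {
    NA
  }
  out <- data.frame(parcel = seq_len(ncol(R)), network = network,
                    cohens_d = d, mean_r = colMeans(R),
                    sd_r = apply(R, 2, stats::sd), n = n)
  class(out) <- c("effect_table", "data.frame")
  out
}
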