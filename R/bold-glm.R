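#' Construct a parcellated BOLD run
#'
#' @param signal Parcels x frames matrix of BOLD values.
#' @param tr_s Sampling interval in seconds (default 0.8).
#' @param confounds Frames x 9 matrix: 6 motion parameters followed by the
#'   white-matter, CSF and whole-brain mean series (may be `NULL`).
#' @param coupling Optional per-parcel generating coupling (ground truth).
#' @param t0_s Acquisition time of the first retained frame, relative to
#'   the run's trial onsets.
#' @return A list of class `bold_run`.
#' @export
bold_run <- function(signal, tr_s = 0.8, confounds = NULL, coupling = NULL,
                     t0_s = 0) {
  signal <- as.matrix(signal)
  if (anyNA(signal)) stop("BOLD signal must not contain missing values")
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != ncol(signal)) {
      stop("confound rows must match BOLD frames")
    }
  }
  structure(list(signal = signal, tr_s = tr_s, confounds = confounds,
                 coupling = coupling, t0_s = t0_s),
            class = "bold_run")
}

#' Drop initial frames and normalize parcel time-series
#'
#' Removes the first `n_drop_frames` frames (from the signal and the
#' confounds, shifting the run's time origin accordingly) and normalizes
#' each parcel's series. Mode "mean100" scales each series to mean 100,
#' the conventional percent-of-mean scaling; "none" leaves values untouched.
#'
#' @param run A [bold_run()].
#' @param n_drop_frames Number of initial frames to discard.
#' @param normalize "mean100" or "none".
#' @return The preprocessed [bold_run()].
#' @export
preprocess_bold <- function(run, n_drop_frames = 8L,
                            normalize = c("mean100", "none")) {
  stopifnot(inherits(run, "bold_run"))
  normalize <- match.arg(normalize)
  n <- ncol(run$signal)
  if (n_drop_frames < 0 || n_drop_frames >= n) {
    stop("n_drop_frames must be in [0, frames)")
  }
  if (n_drop_frames > 0) {
    run$signal <- run$signal[, -(seq_len(n_drop_frames)), drop = FALSE]
    if (!is.null(run$confounds)) {
      run$confounds <- run$confounds[-(seq_len(n_drop_frames)), ,
                                     drop = FALSE]
    }
    run$t0_s <- run$t0_s + n_drop_frames * run$tr_s
  }
  if (normalize == "mean100") {
    m <- rowMeans(run$signal)
    safe <- is.finite(m) & abs(m) > 1e-12
    run$signal[safe, ] <- run$signal[safe, , drop = FALSE] / m[safe] * 100
    run$signal[!safe, ] <- run$signal[!safe, , drop = FALSE] -
      m[!safe] + 100
  }
  run
}

#' Expand motion and tissue series into the 21-parameter confound model
#'
#' Builds the standard nuisance set: the six rigid-body motion parameters,
#' their first temporal derivatives (backward differences, first row
#' zero-padded), their squares, and the white-matter, CSF and whole-brain
#' mean signals — 21 columns in total.
#'
#' @param motion6 Frames x 6 motion matrix, or a frames x 9 matrix whose
#'   last three columns are the tissue means.
#' @param tissue3 Frames x 3 tissue-mean matrix (WM, CSF, global) when
#'   `motion6` has only the motion columns.
#' @return A frames x 21 matrix.
#' @export
build_confound_matrix <- function(motion6, tissue3 = NULL) {
  motion6 <- as.matrix(motion6)
  if (is.null(tissue3)) {
    if (ncol(motion6) != 9) {
      stop("supply motion (6 cols) + tissue (3 cols), or one 9-column matrix")
    }
    tissue3 <- motion6[, 7:9, drop = FALSE]
    motion6 <- motion6[, 1:6, drop = FALSE]
  }
  tissue3 <- as.matrix(tissue3)
  if (ncol(motion6) != 6) stop("expected 6 motion columns")
  if (ncol(tissue3) != 3) stop("expected 3 tissue-mean columns")
  if (nrow(tissue3) != nrow(motion6)) stop("row counts differ")
  d <- rbind(0, diff(motion6))
  out <- cbind(motion6, d, motion6^2, tissue3)
  colnames(out) <- c(paste0("mot", 1:6), paste0("dmot", 1:6),
                     paste0("mot", 1:6, "_sq"), "wm", "csf", "global")
  stopifnot(ncol(out) == 21)
  out
}

#' Remove nuisance signal by ordinary least squares
#'
#' Projects each parcel's time-series onto the orthogonal complement of the
#' confound columns (an intercept is always included). Collinear confound
#' columns are handled by pivoting with a warning; residuals are exact
#' regardless.
#'
#' @param signal Parcels x frames matrix (or a [bold_run()], in which case
#'   its stored confounds are expanded via [build_confound_matrix()]).
#' @param confounds Frames x q confound matrix.
#' @return Parcels x frames residual matrix.
#' @export
regress_nuisance <- function(signal, confounds = NULL) {
  if (inherits(signal, "bold_run")) {
    if (is.null(confounds)) confounds <- build_confound_matrix(signal$confounds)
    signal <- signal$signal
  }
  signal <- as.matrix(signal)
  confounds <- as.matrix(confounds)
  if (ncol(signal) != nrow(confounds)) {
    stop("confound rows must equal BOLD frames")
  }
  if (ncol(signal) < ncol(confounds) + 2) {
    stop("too few frames for the confound model")
  }
  X <- cbind(1, confounds)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("confound matrix is rank deficient; collinear columns dropped")
  }
  t(qr.resid(qrX, t(signal)))
}

#' Build an amplitude-modulated regressor from an attentional series
#'
#' Places an impulse at each trial onset with amplitude equal to the
#' (mean-centered, per run) series value, then convolves the impulse train
#' with the HRF sampled on the frame grid. Onsets are assigned to the
#' nearest frame.
#'
#' @param series A one-run [attention_series()] (or any data frame with
#'   `value` and `onset_s` columns).
#' @param tr_s Frame interval in seconds.
#' @param n_frames Number of frames in the run.
#' @param hrf An [hrf_spec()] (Gaussian by default).
#' @param t0_s Time of the first frame relative to the onsets (nonzero
#'   after frame dropping).
#' @param center Mean-center the amplitudes (default TRUE), so the
#'   regressor carries trial-to-trial modulation, not the mean response.
#' @return Numeric regressor of length `n_frames`.
#' @export
build_am_regressor <- function(series, tr_s, n_frames,
                               hrf = hrf_spec("gaussian"), t0_s = 0,
                               center = TRUE) {
  onset <- series$onset_s
  amp <- series$value
  if (anyNA(amp)) stop("series must be complete")
  if (center) amp <- amp - mean(amp)
  rel <- onset - t0_s
  idx <- round(rel / tr_s) + 1L
  if (any(idx > n_frames)) stop("trial onset beyond run end")
  keep <- idx >= 1L  # trials inside dropped initial frames are not modeled
  stick <- numeric(n_frames)
  for (i in which(keep)) stick[idx[i]] <- stick[idx[i]] + amp[i]
  k <- hrf_kernel(hrf, tr_s)
  out <- stats::convolve(stick, rev(k), type = "open")
  out[seq_len(n_frames)]
}

#' Per-parcel amplitude-modulated GLM fit
#'
#' Ordinary least squares of each parcel's (nuisance-cleaned) time-series
#' on the AM regressor plus an intercept.
#'
#' @param residuals Parcels x frames matrix.
#' @param regressor Numeric vector of length frames.
#' @param label Regressor label carried in the result.
#' @return A data frame of class `glm_result`: `unit`, `beta`, `var`,
#'   `tstat`, `dof`; attribute `regressor_label`.
#' @export
fit_am_glm <- function(residuals, regressor, label = "am") {
  Y <- as.matrix(residuals)
  n <- ncol(Y)
  stopifnot(length(regressor) == n)
  xc <- regressor - mean(regressor)
  sxx <- sum(xc^2)
  if (sxx <= 0) stop("regressor has zero variance")
  yc <- Y - rowMeans(Y)
  beta <- as.vector(yc %*% xc) / sxx
  rss <- pmax(rowSums(yc^2) - beta^2 * sxx, 0)
  dof <- n - 2L
  sigma2 <- rss / dof
  v <- sigma2 / sxx
  res <- data.frame(unit = seq_len(nrow(Y)), beta = beta, var = v,
                    tstat = beta / sqrt(pmax(v, .Machine$double.xmin)),
                    dof = dof)
  attr(res, "regressor_label") <- label
  class(res) <- c("glm_result", "data.frame")
  res
}

#' Combine per-run GLM results with fixed effects
#'
#' Inverse-variance weighted average across runs:
#' `beta = sum(b_i / v_i) / sum(1 / v_i)`, `var = 1 / sum(1 / v_i)`.
#' Runs with non-finite variance get zero weight; a run with zero variance
#' dominates (its beta is exact). Units with no usable run are `NA`.
#'
#' @param results List of `glm_result` data frames over the same units.
#' @return A `glm_result` data frame with `beta`, `var` and a normal
#'   `zstat = beta / sqrt(var)`.
#' @export
combine_runs_fixed_effects <- function(results) {
  stopifnot(length(results) >= 1)
  units <- results[[1]]$unit
  B <- vapply(results, function(r) r$beta, numeric(length(units)))
  V <- vapply(results, function(r) r$var, numeric(length(units)))
  B <- matrix(B, nrow = length(units))
  V <- matrix(V, nrow = length(units))
  W <- ifelse(is.finite(V) & V > 0, 1 / V, 0)
  usable <- is.finite(V) & is.finite(B)
  beta <- rowSums(B * W, na.rm = TRUE) / rowSums(W)
  v <- 1 / rowSums(W)
  # exact runs (zero variance) dominate
  exact <- is.finite(V) & V == 0
  has_exact <- rowSums(exact) > 0
  if (any(has_exact)) {
    beta[has_exact] <- rowSums(B * exact, na.rm = TRUE)[has_exact] /
      rowSums(exact)[has_exact]
    v[has_exact] <- 0
  }
  none <- rowSums(usable) == 0
  beta[none] <- NA_real_
  v[none] <- NA_real_
  res <- data.frame(unit = units, beta = beta, var = v,
                    zstat = beta / sqrt(pmax(v, .Machine$double.xmin)))
  class(res) <- c("glm_result", "data.frame")
  res
}

#' Group-level map from per-subject betas
#'
#' Tests, per unit, whether the mean subject beta differs from zero,
#' optionally adjusting for covariates (numeric covariates are centered,
#' so the intercept is the adjusted group mean). The intercept t statistic
#' is mapped to a z value through the normal quantile of the t CDF and
#' capped at `±z_cap` to keep degenerate units finite.
#'
#' @param betas Subjects x units matrix of subject-level betas.
#' @param covariates Optional data frame (e.g., `age`, `sex`) with one row
#'   per subject; `NULL` for an unadjusted one-sample test.
#' @param z_cap Cap on |z| (default 40).
#' @param label Model label carried on the map.
#' @return A data frame of class `group_map`: `unit`, `beta` (group mean /
#'   adjusted mean), `tstat`, `zstat`; attributes `n_subjects`, `model`.
#' @export
group_level_glm <- function(betas, covariates = NULL, z_cap = 40,
                            label = "model") {
  Y <- as.matrix(betas)
  n <- nrow(Y)
  if (n < 3) stop("need at least 3 subjects")
  if (is.null(covariates)) {
    X <- matrix(1, n, 1)
  } else {
    covariates <- as.data.frame(covariates)
    keep <- vapply(covariates, function(col) length(unique(col)) > 1,
                   logical(1))
    if (!all(keep)) {
      warning("dropping constant covariate(s): ",
              paste(names(covariates)[!keep], collapse = ", "))
      covariates <- covariates[, keep, drop = FALSE]
    }
    if (ncol(covariates) == 0) {
      X <- matrix(1, n, 1)
    } else {
      X <- stats::model.matrix(~ ., data = covariates)
      for (j in 2:ncol(X)) X[, j] <- X[, j] - mean(X[, j])
    }
  }
  p <- ncol(X)
  dof <- n - p
  if (dof < 1) stop("not enough subjects for the covariate model")
  XtXi <- solve(crossprod(X))
  coef <- XtXi %*% crossprod(X, Y)
  resid <- Y - X %*% coef
  sigma2 <- colSums(resid^2) / dof
  se <- sqrt(sigma2 * XtXi[1, 1])
  b0 <- coef[1, ]
  tstat <- ifelse(se > 0, b0 / se, sign(b0) * Inf)
  if (any(!is.finite(tstat) & b0 != 0)) {
    warning("zero residual variance in some units; z capped")
  }
  z <- sign(tstat) * stats::qnorm(
    stats::pt(abs(tstat), dof, lower.tail = FALSE, log.p = TRUE),
    lower.tail = FALSE, log.p = TRUE)
  z[is.na(z) & b0 == 0] <- 0
  z <- pmin(pmax(z, -z_cap), z_cap)
  res <- data.frame(unit = seq_len(ncol(Y)), beta = b0, tstat = tstat,
                    zstat = z)
  attr(res, "n_subjects") <- n
  attr(res, "model") <- label
  class(res) <- c("group_map", "data.frame")
  res
}
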