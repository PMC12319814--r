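# Two-state Gaussian hidden Markov model for RT time-series.
#
# Implemented directly (scaled forward-backward, Baum-Welch EM, Viterbi)
# rather than through a fitted-model wrapper so that the log-likelihood
# trace, posteriors and relabeling behavior are fully under the package's
# control and testable.

# Emission densities, n x k, floored away from zero for numerical safety.
hmm_emission_dens <- function(x, means, variances) {
  k <- length(means)
  dens <- vapply(seq_len(k), function(j)
    stats::dnorm(x, means[j], sqrt(variances[j])), numeric(length(x)))
  pmax(matrix(dens, ncol = k), 1e-300)
}

# Scaled forward-backward pass. Returns per-trial posteriors (gamma),
# summed transition counts (xi_sum) and the data log-likelihood.
hmm_forward_backward <- function(dens, startprob, transmat) {
  n <- nrow(dens); k <- ncol(dens)
  alpha <- matrix(0, n, k)
  scale <- numeric(n)
  a <- startprob * dens[1, ]
  scale[1] <- sum(a)
  alpha[1, ] <- a / scale[1]
  for (t in 2:n) {
    a <- as.vector(alpha[t - 1, ] %*% transmat) * dens[t, ]
    scale[t] <- sum(a)
    alpha[t, ] <- a / scale[t]
  }
  beta <- matrix(0, n, k)
  beta[n, ] <- 1
  xi_sum <- matrix(0, k, k)
  for (t in (n - 1):1) {
    db <- dens[t + 1, ] * beta[t + 1, ]
    beta[t, ] <- as.vector(transmat %*% db) / scale[t + 1]
    xi_sum <- xi_sum +
      (alpha[t, ] %o% db) * transmat / scale[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, xi_sum = xi_sum, loglik = sum(log(scale)))
}

# Most likely state path (log-space Viterbi).
hmm_viterbi <- function(dens, startprob, transmat) {
  n <- nrow(dens); k <- ncol(dens)
  logd <- log(dens)
  logt <- log(pmax(transmat, 1e-300))
  delta <- matrix(-Inf, n, k)
  psi <- matrix(0L, n, k)
  delta[1, ] <- log(pmax(startprob, 1e-300)) + logd[1, ]
  for (t in 2:n) {
    for (j in seq_len(k)) {
      cand <- delta[t - 1, ] + logt[, j]
      psi[t, j] <- which.max(cand)
      delta[t, j] <- cand[psi[t, j]] + logd[t, j]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

hmm_random_init <- function(x, k) {
  means <- as.vector(stats::quantile(x, sort(stats::runif(k, 0.1, 0.9))))
  v <- stats::var(x) * length(x) / max(length(x) - 1, 1)
  stay <- stats::runif(k, 0.7, 0.95)
  transmat <- matrix((1 - stay) / (k - 1), k, k)
  diag(transmat) <- stay
  list(means = means, variances = rep(max(v, 1e-4), k),
       transmat = transmat, startprob = rep(1 / k, k))
}

#' Fit a Gaussian hidden Markov model to an RT series by Baum-Welch
#'
#' Models the trial series as emissions from `n_states` latent attentional
#' states, each with a Gaussian emission distribution, connected by a
#' row-stochastic transition matrix. Parameters are estimated by
#' expectation-maximization (Baum-Welch) using a scaled forward-backward
#' pass; the best of `n_restarts` random initializations (means drawn from
#' the data quantiles) is kept by final log-likelihood. Emission variances
#' are floored at `var_floor` to prevent degenerate collapse.
#'
#' States are relabeled so that state 1 is the state with the longer mean
#' RT; the returned `state_prob` is then the per-trial posterior probability
#' of being in the slow ("lapsing") state, and correlates positively with
#' RT.
#'
#' @param x Numeric vector of complete RT values (typically the z-scored,
#'   interpolated series with runs concatenated), or a list of complete
#'   [rt_series()] objects to concatenate.
#' @param n_states Number of latent states (default 2).
#' @param n_restarts Random restarts (default 10).
#' @param tol EM stops when the log-likelihood improves by less than this.
#' @param max_iter Maximum EM iterations per restart; 0 returns the
#'   initialization unchanged with `converged = FALSE`.
#' @param var_floor Lower bound on emission variances.
#' @param seed Optional integer seed for the restarts.
#'
#' @return A list of class `hmm_fit`: `means`, `variances`, `transmat`,
#'   `startprob`, `log_likelihood`, `ll_trace` (nondecreasing), `converged`,
#'   `state_prob` (posterior of the slow state per trial), `posterior` (full
#'   n x k matrix), `viterbi_path` (0/1 after relabeling), `relabeled`,
#'   `n_obs`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(100, -0.8, 0.5), rnorm(100, 0.8, 0.5))
#' fit <- fit_gaussian_hmm(x, seed = 1)
#' fit$means  # ascending
#' @export
fit_gaussian_hmm <- function(x, n_states = 2L, n_restarts = 10L,
                             tol = 1e-4, max_iter = 500L,
                             var_floor = 1e-4, seed = NULL) {
  if (is.list(x)) {
    x <- unlist(lapply(x, function(s) {
      if (inherits(s, "rt_series")) s$value else as.numeric(s)
    }), use.names = FALSE)
  }
  x <- as.numeric(x)
  if (anyNA(x)) stop("series must be complete (no missing values)")
  k <- as.integer(n_states)
  if (length(x) < 2L * k) stop("need at least 2 * n_states observations")
  if (!is.null(seed)) set.seed(as.integer(seed))

  best <- NULL
  for (r in seq_len(max(n_restarts, 1L))) {
    par <- hmm_random_init(x, k)
    trace <- numeric(0)
    converged <- FALSE
    fb <- NULL
    if (max_iter > 0) {
      for (it in seq_len(max_iter)) {
        dens <- hmm_emission_dens(x, par$means, par$variances)
        fb <- hmm_forward_backward(dens, par$startprob, par$transmat)
        trace <- c(trace, fb$loglik)
        # M step
        g <- fb$gamma
        gs <- colSums(g)
        par$startprob <- g[1, ]
        tm <- fb$xi_sum / pmax(rowSums(fb$xi_sum), 1e-300)
        par$transmat <- tm / rowSums(tm)
        par$means <- as.vector(crossprod(g, x)) / gs
        par$variances <- pmax(
          as.vector(crossprod(g, x^2)) / gs - par$means^2, var_floor)
        if (it > 1 && abs(trace[it] - trace[it - 1]) < tol) {
          converged <- TRUE
          break
        }
      }
    }
    # posteriors and likelihood under the final parameters
    dens <- hmm_emission_dens(x, par$means, par$variances)
    fb <- hmm_forward_backward(dens, par$startprob, par$transmat)
    if (max_iter > 0) trace <- c(trace, fb$loglik)
    fit <- list(par = par, fb = fb, trace = trace, converged = converged,
                dens = dens)
    if (is.null(best) || fb$loglik > best$fb$loglik) best <- fit
  }

  par <- best$par
  ord <- order(par$means)            # ascending: last = longest mean RT
  relabeled <- !identical(ord, seq_len(k))
  par$means <- par$means[ord]
  par$variances <- par$variances[ord]
  par$startprob <- par$startprob[ord]
  par$transmat <- par$transmat[ord, ord, drop = FALSE]
  gamma <- best$fb$gamma[, ord, drop = FALSE]
  dens <- best$dens[, ord, drop = FALSE]
  vit <- hmm_viterbi(dens, par$startprob, par$transmat) - 1L

  structure(list(
    means = par$means,
    variances = par$variances,
    transmat = par$transmat,
    startprob = par$startprob,
    log_likelihood = best$fb$loglik,
    ll_trace = best$trace,
    converged = best$converged,
    state_prob = gamma[, k],
    posterior = gamma,
    viterbi_path = vit,
    relabeled = relabeled,
    n_obs = length(x)
  ), class = "hmm_fit")
}
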