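#' Threshold a statistic map into signed masks
#'
#' @param values Finite per-unit map (e.g., group z values).
#' @param z_threshold Nonnegative threshold.
#' @return A list of class `signed_mask`: `positive` (unit indices with
#'   value > threshold), `negative` (value < -threshold), `threshold`,
#'   `n_units`.
#' @export
threshold_map <- function(values, z_threshold) {
  if (z_threshold < 0) stop("threshold must be >= 0")
  if (any(!is.finite(values))) stop("map must be finite")
  structure(list(positive = which(values > z_threshold),
                 negative = which(values < -z_threshold),
                 threshold = z_threshold,
                 n_units = length(values)),
            class = "signed_mask")
}

#' Dice overlap coefficient of two unit sets
#'
#' `2 |A intersect B| / (|A| + |B|)`. Two empty sets have undefined overlap
#' and return `NA`.
#'
#' @param a,b Integer vectors of unit indices (e.g., the `positive` sets of
#'   two [threshold_map()] results).
#' @return A number in \[0, 1\], or `NA` if both sets are empty.
#' @examples
#' dice_score(1:4, 3:6)  # 0.5
#' @export
dice_score <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(NA_real_)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Percent of each network covered by a mask
#'
#' @param mask Integer vector of parcel indices (one side of a
#'   [threshold_map()] result).
#' @param parcellation Parcellation table with `parcel` and `network`
#'   columns (see [synthetic_parcellation()]).
#' @return Data frame: `network`, `n_parcels`, `n_in_mask`, `coverage_pct`.
#' @export
network_coverage <- function(mask, parcellation) {
  if (length(mask) && (any(mask < 1) || any(mask > nrow(parcellation)))) {
    stop("mask indices outside the parcellation")
  }
  g <- factor(parcellation$network)
  tot <- table(g)
  inm <- table(g[parcellation$parcel %in% mask])
  data.frame(network = names(tot),
             n_parcels = as.vector(tot),
             n_in_mask = as.vector(inm),
             coverage_pct = 100 * as.vector(inm) / as.vector(tot))
}

# Empirical variogram over distance bins: mean of 0.5 (v_i - v_j)^2 among
# pairs whose distance falls in the bin. Bins are distance quantiles up to
# the 75th percentile (long-range pairs are uninformative).
empirical_variogram <- function(values, dmat, n_bins = 20) {
  iu <- upper.tri(dmat)
  dd <- dmat[iu]
  vv <- 0.5 * outer(values, values, "-")[iu]^2
  keep <- dd <= stats::quantile(dd, 0.75)
  dd <- dd[keep]; vv <- vv[keep]
  br <- stats::quantile(dd, seq(0, 1, length.out = n_bins + 1))
  bin <- findInterval(dd, br, rightmost.closed = TRUE)
  bin[bin < 1] <- 1; bin[bin > n_bins] <- n_bins
  tapply(vv, factor(bin, levels = seq_len(n_bins)), mean)
}

# Gaussian distance-kernel smoother matrix, row-normalized.
distance_smoother <- function(dmat, bandwidth) {
  w <- exp(-dmat^2 / (2 * bandwidth^2))
  w / rowSums(w)
}

#' Variogram-matching spatial surrogates of a brain map
#'
#' Generates surrogate maps that keep the value multiset of `map` (each
#' surrogate is a reordering of the original values) while approximating
#' its spatial autocorrelation: a permuted copy is smoothed over parcel-
#' centroid distances with a Gaussian kernel whose bandwidth is chosen, on
#' pilot permutations, to minimize the squared distance between the
#' surrogate's and the map's empirical variograms; the original values are
#' then rank-remapped onto the smoothed field.
#'
#' @param map Numeric per-unit map.
#' @param centroids Units x 3 coordinate matrix.
#' @param n_surr Number of surrogates.
#' @param seed Optional integer seed.
#' @param n_pilot Pilot permutations per candidate bandwidth.
#' @return Units x `n_surr` matrix of surrogate maps.
#' @export
variogram_surrogates <- function(map, centroids, n_surr, seed = NULL,
                                 n_pilot = 10L) {
  n <- length(map)
  centroids <- as.matrix(centroids)
  stopifnot(nrow(centroids) == n)
  if (!is.null(seed)) set.seed(as.integer(seed))
  dmat <- as.matrix(stats::dist(centroids))
  perms <- matrix(0L, n, n_surr)
  for (j in seq_len(n_surr)) perms[, j] <- sample.int(n)
  vg_obs <- empirical_variogram(map, dmat)
  bandwidths <- stats::quantile(dmat[upper.tri(dmat)],
                                c(0.005, 0.01, 0.02, 0.05, 0.1, 0.2))
  mixes <- c(0, 0.25, 0.5, 0.75)
  sorted_vals <- sort(map)
  std <- function(x) {
    s <- stats::sd(x)
    if (s == 0) return(x - mean(x))
    (x - mean(x)) / s
  }
  # choose (bandwidth, noise mix) on pilot permutations by variogram fit
  grid <- expand.grid(bw = bandwidths, mix = mixes)
  scores <- vapply(seq_len(nrow(grid)), function(gi) {
    W <- distance_smoother(dmat, grid$bw[gi])
    mean(vapply(seq_len(min(n_pilot, n_surr)), function(j) {
      x <- map[perms[, j]]
      field <- (1 - grid$mix[gi]) * std(as.vector(W %*% x)) +
        grid$mix[gi] * std(x)
      sur <- sorted_vals[rank(field, ties.method = "first")]
      sum((empirical_variogram(sur, dmat) - vg_obs)^2)
    }, numeric(1)))
  }, numeric(1))
  gi <- which.min(scores)
  W <- distance_smoother(dmat, grid$bw[gi])
  mix <- grid$mix[gi]
  X <- matrix(map[perms], n, n_surr)
  SM <- W %*% X
  vapply(seq_len(n_surr), function(j) {
    field <- (1 - mix) * std(SM[, j]) + mix * std(X[, j])
    sorted_vals[rank(field, ties.method = "first")]
  }, numeric(n))
}

#' Correlate two brain maps against a spatial permutation null
#'
#' The observed statistic is the Pearson correlation between `mapA` and
#' `mapB` across units. The null distribution is built from surrogates of
#' `mapA`: plain value shuffles (`null_kind = "shuffle"`, appropriate when
#' the map carries no spatial autocorrelation), or variogram-matching
#' surrogates (`null_kind = "variogram"`) that smooth a permuted copy of
#' the map over parcel-centroid distances — with the smoothing bandwidth
#' chosen, on pilot permutations, to best match the map's empirical
#' variogram — and then rank-remap the original values onto the smoothed
#' field, preserving the value multiset while approximating the spatial
#' autocorrelation.
#'
#' The two-sided p-value uses the add-one permutation formula
#' `p = (1 + #(|r_perm| >= |r_obs|)) / (1 + n_perm)`.
#'
#' @param mapA,mapB Numeric per-unit maps over the same units.
#' @param n_perm Number of permutations (default 10,000).
#' @param null_kind "shuffle" or "variogram".
#' @param centroids Units x 3 coordinate matrix (required for
#'   "variogram"); e.g., the `x`,`y`,`z` columns of
#'   [synthetic_parcellation()].
#' @param seed Integer seed.
#' @param n_pilot Pilot permutations used to pick the bandwidth.
#' @return A list of class `null_model_result`: `observed_r`, `perm_r`,
#'   `p_value`, `n_perm`, `null_kind`.
#' @export
spatial_null_correlation <- function(mapA, mapB, n_perm = 10000L,
                                     null_kind = c("shuffle", "variogram"),
                                     centroids = NULL, seed = NULL,
                                     n_pilot = 10L) {
  null_kind <- match.arg(null_kind)
  n <- length(mapA)
  stopifnot(length(mapB) == n, n >= 3, n_perm >= 100)
  if (stats::sd(mapA) == 0 || stats::sd(mapB) == 0) {
    stop("constant map: correlation undefined")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  r_obs <- stats::cor(mapA, mapB)

  if (null_kind == "shuffle") {
    S <- vapply(seq_len(n_perm), function(j) mapA[sample.int(n)],
                numeric(n))
  } else {
    if (is.null(centroids)) stop("variogram null requires centroids")
    S <- variogram_surrogates(mapA, centroids, n_perm, n_pilot = n_pilot)
  }
  bc <- mapB - mean(mapB)
  num <- as.vector(crossprod(S, bc))
  s_mean <- colMeans(S)
  s_sd <- sqrt(colSums(S^2) / n - s_mean^2)
  perm_r <- (num / n) / (s_sd * stats::sd(mapB) * sqrt((n - 1) / n))
  p <- (1 + sum(abs(perm_r) >= abs(r_obs))) / (1 + n_perm)
  structure(list(observed_r = r_obs, perm_r = perm_r, p_value = p,
                 n_perm = n_perm, null_kind = null_kind),
            class = "null_model_result")
}
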