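#' Synthetic functional parcellation for testing
#'
#' Builds a Gordon-style parcellation table: `n_parcels` parcels, each
#' assigned to exactly one of `n_networks` functional networks, with
#' synthetic 3D centroid coordinates (network centers scattered in a brain-
#' sized box, parcels clustered around their network center). The defaults
#' mirror the scale of the 333-parcel / 13-network functional atlas; the
#' coordinates are synthetic and exist only so distance-based operations
#' (variogram null models) are exercised realistically. Real parcellation
#' tables with the same columns can be supplied anywhere this one is used.
#'
#' @param n_parcels Number of parcels (default 333).
#' @param n_networks Number of networks (default 13).
#' @param seed Integer seed for the synthetic coordinates.
#' @return A data frame: `parcel` (1..n), `network` (factor), `x`, `y`, `z`
#'   (mm-scale synthetic centroids).
#' @export
synthetic_parcellation <- function(n_parcels = 333L, n_networks = 13L,
                                   seed = 1L) {
  stopifnot(n_parcels >= n_networks, n_networks >= 1)
  set.seed(as.integer(seed))
  net_names <- c("default", "dorsal_attn", "ventral_attn",
                 "cingulo_opercular", "frontoparietal", "salience",
                 "somatomotor_hand", "somatomotor_mouth", "visual",
                 "auditory", "retrosplenial", "cingulo_parietal", "none")
  if (n_networks <= length(net_names)) {
    nets <- net_names[seq_len(n_networks)]
  } else {
    nets <- c(net_names, paste0("net", seq_len(n_networks - length(net_names))))
  }
  # near-even split of parcels across networks
  sizes <- rep(n_parcels %/% n_networks, n_networks)
  extra <- n_parcels - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  network <- rep(nets, sizes)
  centers <- matrix(stats::runif(3 * n_networks, -60, 60), ncol = 3)
  idx <- rep(seq_len(n_networks), sizes)
  xyz <- centers[idx, , drop = FALSE] +
    matrix(stats::rnorm(3 * n_parcels, 0, 12), ncol = 3)
  data.frame(parcel = seq_len(n_parcels),
             network = factor(network, levels = nets),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

#' Average unit-level values within labels
#'
#' Unweighted mean of the rows of `values` within each label (e.g., voxels
#' into parcels, or parcels into networks). Labels with no units yield
#' `NA`.
#'
#' @param values Numeric vector (one value per unit) or matrix with one row
#'   per unit.
#' @param labels Label per unit (parcel or network id).
#' @return A vector or matrix with one row per distinct label, ordered by
#'   label; row names carry the labels.
#' @export
aggregate_parcels <- function(values, labels) {
  vec <- is.null(dim(values))
  M <- if (vec) matrix(values, ncol = 1) else as.matrix(values)
  if (nrow(M) != length(labels)) stop("one label per unit required")
  g <- factor(labels)
  counts <- table(g)                        # keeps empty levels
  sums <- rowsum(M, g)                      # drops empty levels
  out <- matrix(NA_real_, nlevels(g), ncol(M),
                dimnames = list(levels(g), colnames(M)))
  out[rownames(sums), ] <- sums / as.vector(counts[rownames(sums)])
  if (vec) out[, 1] else out
}
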