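#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive their mean rank), the
#' standard Spearman definition. Used both voxelwise (descriptively) and at
#' parcel level (for inference via the spin test).
#'
#' @param x,y numeric vectors of equal length >= 3, finite, each with nonzero
#'   variance.
#' @return correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("'x' and 'y' must have equal length >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sx <- stats::sd(rx); sy <- stats::sd(ry)
  if (sx == 0 || sy == 0) stop("zero-variance input")
  mean((rx - mean(rx)) * (ry - mean(ry))) / (sx * sy) * length(x) / (length(x) - 1)
}

#' Uniform random 3D rotation
#'
#' Draws a rotation matrix from the Haar (uniform) distribution on SO(3) by
#' QR-orthonormalizing a matrix of standard Gaussian entries, fixing the signs
#' of the diagonal of R, and flipping one column if the determinant is -1.
#'
#' @return a 3x3 orthogonal matrix with determinant +1. Consumes the R random
#'   stream; seed with [set.seed()] for reproducibility.
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3L, 3L))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

#' Rotate parcel data on the sphere
#'
#' Applies a rotation to the parcel centroids and reassigns each parcel the
#' value of the parcel whose original centroid is nearest (maximum dot
#' product) to its rotated position. The reassignment is a surjection: values
#' may be duplicated or dropped when the rotated geometry is uneven, the
#' standard behaviour of the spin-test family.
#'
#' @param values numeric vector, one value per parcel (ordered as
#'   `parc$parcel_ids`).
#' @param parc a [parcellation()] with unit-sphere centroids.
#' @param rotation 3x3 rotation matrix.
#' @return permuted values (same length).
#' @export
spin_permute <- function(values, parc, rotation) {
  C <- parc$centroids
  if (is.null(C)) stop("parcellation has no centroids")
  if (length(values) != nrow(C)) stop("one value per parcel required")
  rotated <- C %*% t(rotation)
  assign <- max.col(rotated %*% t(C), ties.method = "first")
  values[assign]
}

#' Spin permutation test for the correlation of two parcel maps
#'
#' Computes the observed Spearman correlation between two parcel vectors and
#' builds a spatial null by rotating the first map's parcel values on the
#' sphere `n_perm` times, correlating each rotated map with the unrotated
#' second map. Rotation preserves the map's spatial autocorrelation, so the
#' null is not inflated the way an i.i.d. permutation null would be. The
#' two-sided p-value uses the add-one correction
#' `p = (1 + #\{|null| >= |rho|\}) / (n_perm + 1)`, hence is never below
#' `1 / (n_perm + 1)`.
#'
#' @inheritParams spin_permute
#' @param x,y numeric parcel vectors (ordered as `parc$parcel_ids`).
#' @param n_perm number of rotations (default 10000).
#' @param seed integer seed for the rotation stream.
#' @param keep_rotations store the rotation matrices in the result (memory
#'   heavy at the default `n_perm`; off by default).
#' @return list with elements `rho`, `p_spin`, and `null` (a `spin_null`
#'   object with fields `n_perm`, `seed`, `null_rhos`, optionally
#'   `rotations`).
#' @export
spin_test <- function(x, y, parc, n_perm = 10000L, seed = 1L,
                      keep_rotations = FALSE) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  rho_obs <- spearman_rho(x, y)
  C <- parc$centroids
  Ct <- t(C)
  ry <- rank(y, ties.method = "average")
  ry_c <- ry - mean(ry)
  n <- length(x)
  null_rhos <- numeric(n_perm)
  rotations <- if (keep_rotations) vector("list", n_perm) else NULL
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  for (k in seq_len(n_perm)) {
    R <- random_rotation()
    assign <- max.col((C %*% t(R)) %*% Ct, ties.method = "first")
    rx <- rank(x[assign], ties.method = "average")
    rx_c <- rx - mean(rx)
    denom <- sqrt(sum(rx_c^2) * sum(ry_c^2))
    null_rhos[k] <- if (denom == 0) 0 else sum(rx_c * ry_c) / denom
    if (keep_rotations) rotations[[k]] <- R
  }
  p <- (1 + sum(abs(null_rhos) >= abs(rho_obs))) / (n_perm + 1)
  null <- structure(list(n_perm = n_perm, seed = seed,
                         null_rhos = null_rhos, rotations = rotations),
                    class = "spin_null")
  list(rho = rho_obs, p_spin = p, null = null)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: with sorted p-values `p_(1) <= ... <= p_(m)`, find the
#' largest `k` with `p_(k) <= k * alpha / m` and reject hypotheses 1..k.
#'
#' @param pvals numeric vector of p-values in (0, 1\].
#' @param alpha FDR level in (0, 1), default 0.05.
#' @return logical vector, `TRUE` where the hypothesis is rejected.
#' @export
fdr_bh <- function(pvals, alpha = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  m <- length(pvals)
  ord <- order(pvals)
  below <- which(pvals[ord] <= seq_len(m) * alpha / m)
  reject <- logical(m)
  if (length(below)) reject[ord[seq_len(max(below))]] <- TRUE
  reject
}

#' Correlate map pairs with spin-test inference and FDR correction
#'
#' For each requested pair of named maps, computes the voxelwise Spearman
#' correlation (descriptive only: voxel-level p-values would be inflated by
#' spatial autocorrelation), the parcel-level Spearman correlation of parcel
#' medians, and a spin-test p-value; then flags significance across the whole
#' family of pairs with Benjamini-Hochberg FDR.
#'
#' @param maps named list of [volume_map()] objects on one grid.
#' @param pairs two-column character matrix (or data.frame) of map names.
#' @param mask logical 3D array.
#' @param parc a [parcellation()].
#' @param n_perm,alpha,seed spin-test and FDR settings.
#' @return data.frame with columns `map_a`, `map_b`, `rho_voxel`,
#'   `rho_parcel`, `p_spin`, `q_flag`, `n_perm`, `seed`.
#' @export
correlate_pairs <- function(maps, pairs, mask, parc,
                            n_perm = 10000L, alpha = 0.05, seed = 1L) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("'pairs' must have two columns")
  pv <- lapply(maps, function(m) parcel_medians(m, parc))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    if (is.null(maps[[a]]) || is.null(maps[[b]]))
      stop("unknown map name in pair: ", a, " / ", b)
    st <- spin_test(pv[[a]], pv[[b]], parc, n_perm = n_perm,
                    seed = seed + i - 1L)
    data.frame(map_a = a, map_b = b,
               rho_voxel = spearman_rho(mask_values(maps[[a]], mask),
                                        mask_values(maps[[b]], mask)),
               rho_parcel = st$rho, p_spin = st$p_spin,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_flag <- fdr_bh(out$p_spin, alpha)
  out$n_perm <- n_perm
  out$seed <- seed
  out
}

# Seed handling: run a block under a given seed, then restore the caller's
# random stream so library code does not clobber user-level reproducibility.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
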