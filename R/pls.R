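#' Two-block partial least squares, canonical mode
#'
#' Finds paired unit-norm weight vectors over the two blocks' channels whose
#' latent scores (voxels projected onto the weights) have maximal covariance,
#' extracting components one at a time with the NIPALS power iteration and
#' deflating both blocks by their own scores (canonical mode, symmetric in
#' the two blocks). Columns are standardized to mean 0, SD 1 before fitting
#' and the preprocessing is recorded in the model. Component signs are fixed
#' by making each component's largest-magnitude X weight positive (the
#' paired Y weight is flipped jointly), so fits are deterministic.
#'
#' @param X,Y numeric matrices, voxels (within the analysis mask) in rows and
#'   channels in columns; same row count, >= 2 columns each, more rows than
#'   columns.
#' @param n_components number of components to extract (default 2; the
#'   workflow analyzes only the first two).
#' @param tol convergence tolerance on the X-weight update (default 1e-6).
#' @param max_iter power-iteration cap per component (default 500).
#' @return object of class `"pls_model"`: `weights_x`, `weights_y`
#'   (channels x components, unit columns), `scores_x`, `scores_y`
#'   (voxels x components), `score_cov` (per-component score covariance),
#'   `column_means_x/y`, `column_sds_x/y`, `n_components`, `n_iter`.
#' @export
fit_pls <- function(X, Y, n_components = 2L, tol = 1e-6, max_iter = 500L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same rows (voxels)")
  if (ncol(X) < 2L || ncol(Y) < 2L) stop("each block needs >= 2 channels")
  if (nrow(X) < max(ncol(X), ncol(Y)))
    stop("need at least as many voxels as channels")
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(ncol(X), ncol(Y)))
    stop("n_components must lie in 1..min(channel counts)")
  std <- function(M) {
    mu <- colMeans(M)
    sd_ <- apply(M, 2L, stats::sd)
    if (any(sd_ == 0)) stop("rank-deficient block: zero-variance channel")
    list(Z = sweep(sweep(M, 2L, mu), 2L, sd_, "/"), mu = mu, sd = sd_)
  }
  sx <- std(X); sy <- std(Y)
  Xr <- sx$Z; Yr <- sy$Z
  px <- ncol(X); py <- ncol(Y); n <- nrow(X)
  Wx <- matrix(0, px, n_components, dimnames = list(colnames(X), NULL))
  Wy <- matrix(0, py, n_components, dimnames = list(colnames(Y), NULL))
  Tx <- matrix(0, n, n_components)
  Ty <- matrix(0, n, n_components)
  n_iter <- integer(n_components)
  eps <- .Machine$double.eps^0.5
  for (k in seq_len(n_components)) {
    u <- Yr[, 1L]
    if (sum(u^2) < eps) stop("rank-deficient Y block at component ", k)
    w_old <- rep(Inf, px)
    it <- 0L
    repeat {
      it <- it + 1L
      w <- crossprod(Xr, u)
      nw <- sqrt(sum(w^2))
      if (nw < eps) stop("rank-deficient X block at component ", k)
      w <- w / nw
      t_ <- Xr %*% w
      c_ <- crossprod(Yr, t_)
      nc <- sqrt(sum(c_^2))
      if (nc < eps) stop("rank-deficient Y block at component ", k)
      c_ <- c_ / nc
      u <- Yr %*% c_
      if (sum((w - w_old)^2) < tol^2) break
      if (it >= max_iter)
        stop("NIPALS did not converge for component ", k,
             " within ", max_iter, " iterations")
      w_old <- w
    }
    # deterministic sign: largest-|weight| X entry positive, Y flipped jointly
    if (w[which.max(abs(w))] < 0) {
      w <- -w; c_ <- -c_; t_ <- -t_; u <- -u
    }
    Wx[, k] <- w; Wy[, k] <- c_
    Tx[, k] <- t_; Ty[, k] <- u
    n_iter[k] <- it
    # canonical-mode deflation: each block regressed on its own scores
    p <- crossprod(Xr, t_) / sum(t_^2)
    q <- crossprod(Yr, u) / sum(u^2)
    Xr <- Xr - tcrossprod(t_, p)
    Yr <- Yr - tcrossprod(u, q)
  }
  structure(list(weights_x = Wx, weights_y = Wy,
                 scores_x = Tx, scores_y = Ty,
                 score_cov = vapply(seq_len(n_components), function(k)
                   stats::cov(Tx[, k], Ty[, k]), numeric(1)),
                 column_means_x = sx$mu, column_sds_x = sx$sd,
                 column_means_y = sy$mu, column_sds_y = sy$sd,
                 n_components = n_components, n_iter = n_iter,
                 scores_normalized = FALSE),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d components, %d voxels; score cov: %s\n",
              x$n_components, nrow(x$scores_x),
              paste(signif(x$score_cov, 4), collapse = ", ")))
  invisible(x)
}

#' Normalize PLS score maps to an absolute maximum of 1
#'
#' Divides each component's score vector (both blocks) by its absolute
#' maximum, the convention used when displaying score maps. Spearman
#' correlations between scores are unaffected.
#'
#' @param model a fitted [fit_pls()] model.
#' @return the model with `scores_x`/`scores_y` rescaled and
#'   `scores_normalized = TRUE`.
#' @export
normalize_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  for (k in seq_len(model$n_components)) {
    mx <- max(abs(model$scores_x[, k]))
    my <- max(abs(model$scores_y[, k]))
    if (mx == 0 || my == 0) stop("all-zero score map in component ", k)
    model$scores_x[, k] <- model$scores_x[, k] / mx
    model$scores_y[, k] <- model$scores_y[, k] / my
  }
  model$scores_normalized <- TRUE
  model
}

#' Spearman correlation between paired block scores
#'
#' @param model a fitted [fit_pls()] model.
#' @return numeric vector, one Spearman correlation per component between
#'   the X-block and Y-block score maps.
#' @export
score_correlations <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  vapply(seq_len(model$n_components), function(k)
    spearman_rho(model$scores_x[, k], model$scores_y[, k]), numeric(1))
}

#' Assemble a voxel-by-channel matrix from named maps
#'
#' @param maps named list of [volume_map()] objects.
#' @param mask logical 3D array; rows are within-mask voxels.
#' @param channels character vector selecting and ordering columns.
#' @return numeric matrix with one column per channel.
#' @export
stack_channels <- function(maps, mask, channels = names(maps)) {
  miss <- setdiff(channels, names(maps))
  if (length(miss)) stop("unknown channels: ", paste(miss, collapse = ", "))
  do.call(cbind, lapply(stats::setNames(channels, channels), function(ch)
    mask_values(maps[[ch]], mask)))
}
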