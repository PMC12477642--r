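# Shared fixtures: everything is generated in code at test time.

# tiny grid with a box mask, for exact hand computations
tiny_grid <- function(d = c(8L, 8L, 8L), vox = 6) {
  mask <- array(FALSE, d)
  mask[3:6, 3:6, 3:6] <- TRUE
  list(d = d, vox = vox, mask = mask)
}

rand_map <- function(d, vox = 6, seed = 1, positive = FALSE) {
  set.seed(seed)
  v <- array(rnorm(prod(d)), d)
  if (positive) v <- exp(v / 2)
  volume_map(v, vox)
}

# constant-weight dynamic series from a vector of frame scalars
const_series <- function(frame_values, times = NULL, d = c(8L, 8L, 8L),
                         vox = 6) {
  if (is.null(times)) times <- (seq_along(frame_values) - 1) * 5
  frames <- lapply(frame_values, function(c) volume_map(array(c, d), vox))
  dynamic_series(frames, times)
}

# small, fully in-memory study for pipeline tests
quick_study_config <- function(seed = 7, n_perm = 200L, ...) {
  run_config(
    simulate = list(mixing = mixing_spec(n_subjects = 4L)),
    n_perm = n_perm, seed = seed, fwhm_mm = 14, ...)
}

# brute-force mask-renormalized Gaussian smoothing (direct triple sum)
brute_smooth <- function(values, fwhm_mm, mask, vox) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / vox
  d <- dim(values)
  r <- max(1L, ceiling(4 * sigma))
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    num <- 0; den <- 0
    for (di in -r:r) for (dj in -r:r) for (dk in -r:r) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
          kk < 1 || kk > d[3]) next
      if (!mask[ii, jj, kk]) next
      w <- exp(-(di^2 + dj^2 + dk^2) / (2 * sigma^2))
      num <- num + w * values[ii, jj, kk]
      den <- den + w
    }
    out[i, j, k] <- num / den
  }
  out
}

# brute-force BH step-up: evaluate every step-up threshold
brute_bh <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[ord[i]] <= i * alpha / m) k <- i
  rej <- logical(m)
  if (k > 0) rej[ord[seq_len(k)]] <- TRUE
  rej
}

# two-parcel parcellation at the sphere poles, for exact spin checks
two_pole_parc <- function() {
  labels <- array(0L, c(8L, 8L, 8L))
  labels[4, 4, 7] <- 1L
  labels[4, 4, 2] <- 2L
  parcellation(labels, rbind(c(0, 0, 1), c(0, 0, -1)), parcel_ids = 1:2)
}
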