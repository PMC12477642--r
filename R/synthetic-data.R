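#' Specifications for the synthetic multi-subject dataset
#'
#' The generator emulates the structure of a paired hyperpolarized-13C /
#' metabolic-PET study on a coarse common grid: a handful of spatially
#' autocorrelated latent fields shared across modalities through known mixing
#' matrices, one latent reserved for a vascular component, multiplicative
#' subject gains (polarization / dose analogs), additive voxel noise, and
#' simple per-channel time courses so integration windows are meaningful.
#'
#' `latent_field_spec` describes the latent Gaussian random fields;
#' `mixing_spec` the channel loadings and noise levels; `dynamic_spec` the
#' frame grid and per-channel time-course weights.
#'
#' @param grid_shape integer triple, each >= 8 (default 32^3).
#' @param voxel_size_mm isotropic voxel size (default 6 mm, coarse like the
#'   15 mm hyperpolarized data after grouping).
#' @param n_latents number of latent fields, 2..10.
#' @param smooth_fwhm_mm autocorrelation scale of the latents (default 15 mm,
#'   the native hyperpolarized resolution).
#' @param seed integer seed.
#' @return a spec object (plain list with a class attribute).
#' @export
latent_field_spec <- function(grid_shape = c(32L, 32L, 32L),
                              voxel_size_mm = 6, n_latents = 3L,
                              smooth_fwhm_mm = 15, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must be three integers, each >= 8")
  if (n_latents < 2L || n_latents > 10L)
    stop("n_latents must lie in 2..10")
  if (voxel_size_mm <= 0 || smooth_fwhm_mm < 0)
    stop("voxel_size_mm must be positive and smooth_fwhm_mm nonnegative")
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 n_latents = as.integer(n_latents),
                 smooth_fwhm_mm = smooth_fwhm_mm, seed = as.integer(seed)),
            class = "latent_field_spec")
}

#' @rdname latent_field_spec
#' @param hp_channels,pet_channels channel names for the two modalities.
#' @param mixing_hp,mixing_pet loading matrices (channels x latents). The
#'   defaults plant one metabolic latent loading lactate/bicarbonate and
#'   CMRglc/CBF/CMRO2, one vascular latent loading pyruvate and CBV, and one
#'   weak nuisance latent.
#' @param vascular_latent_index column index of the vascular latent.
#' @param subject_noise_sd log-scale SD of the per-subject, per-channel
#'   lognormal gain (default 0.2).
#' @param voxel_noise_sd additive voxel noise SD as a fraction of each mixed
#'   map's within-mask SD (default 0.05).
#' @param n_subjects number of subjects, >= 3 (default 35, the study size).
#' @export
mixing_spec <- function(hp_channels = c("pyruvate", "lactate", "bicarbonate"),
                        pet_channels = c("cmrglc", "cbf", "cmro2", "cbv"),
                        mixing_hp = NULL, mixing_pet = NULL,
                        vascular_latent_index = 2L,
                        subject_noise_sd = 0.2,
                        voxel_noise_sd = 0.05,
                        n_subjects = 35L) {
  if (is.null(mixing_hp))
    mixing_hp <- matrix(c(0.2, 1.0, 0.1,    # pyruvate: vascular-dominated
                          1.0, 0.2, 0.1,    # lactate: metabolic
                          0.9, 0.1, 0.1),   # bicarbonate: metabolic
                        nrow = 3L, byrow = TRUE,
                        dimnames = list(hp_channels, NULL))
  if (is.null(mixing_pet))
    mixing_pet <- matrix(c(1.0, 0.10, 0.1,  # cmrglc
                           0.9, 0.20, 0.1,  # cbf
                           0.9, 0.15, 0.1,  # cmro2
                           0.15, 1.0, 0.1), # cbv: vascular-dominated
                         nrow = 4L, byrow = TRUE,
                         dimnames = list(pet_channels, NULL))
  mixing_hp <- as.matrix(mixing_hp); mixing_pet <- as.matrix(mixing_pet)
  if (nrow(mixing_hp) != length(hp_channels) ||
      nrow(mixing_pet) != length(pet_channels))
    stop("mixing matrices must have one row per channel")
  if (ncol(mixing_hp) != ncol(mixing_pet))
    stop("both mixing matrices must use the same latent count")
  if (!all(is.finite(mixing_hp)) || !all(is.finite(mixing_pet)))
    stop("mixing matrices must be finite")
  if (vascular_latent_index < 1L || vascular_latent_index > ncol(mixing_hp))
    stop("invalid vascular_latent_index")
  if (subject_noise_sd < 0 || voxel_noise_sd < 0)
    stop("noise SDs must be nonnegative")
  if (n_subjects < 3L) stop("n_subjects must be >= 3")
  rownames(mixing_hp) <- hp_channels
  rownames(mixing_pet) <- pet_channels
  structure(list(hp_channels = hp_channels, pet_channels = pet_channels,
                 mixing_hp = mixing_hp, mixing_pet = mixing_pet,
                 vascular_latent_index = as.integer(vascular_latent_index),
                 subject_noise_sd = subject_noise_sd,
                 voxel_noise_sd = voxel_noise_sd,
                 n_subjects = as.integer(n_subjects)),
            class = "mixing_spec")
}

#' @rdname latent_field_spec
#' @param n_frames frames per series, >= 3 (default 12, as in the 60 s
#'   hyperpolarized acquisition).
#' @param frame_interval_s frame spacing in seconds (default 5).
#' @param timecourse_shape named list of per-channel nonnegative weight
#'   vectors over frames, each summing to 1. Channels not listed get the
#'   default gamma-like bolus shapes (early pyruvate peak, delayed
#'   lactate/bicarbonate, near-flat PET tracers).
#' @export
dynamic_spec <- function(n_frames = 12L, frame_interval_s = 5,
                         timecourse_shape = list()) {
  if (n_frames < 3L) stop("n_frames must be >= 3")
  if (frame_interval_s <= 0) stop("frame_interval_s must be positive")
  for (w in timecourse_shape) {
    if (any(w < 0) || length(w) != n_frames ||
        abs(sum(w) - 1) > 1e-8)
      stop("each time-course must be nonnegative, length n_frames, sum 1")
  }
  structure(list(n_frames = as.integer(n_frames),
                 frame_interval_s = frame_interval_s,
                 timecourse_shape = timecourse_shape),
            class = "dynamic_spec")
}

# gamma-density bolus over the frame grid, peaking at frame `peak`
bolus_weights <- function(n_frames, peak, shape = 3) {
  t <- seq_len(n_frames)
  w <- stats::dgamma(t, shape = shape, rate = shape / peak)
  w / sum(w)
}

default_timecourse <- function(channel, n_frames) {
  switch(channel,
    pyruvate    = bolus_weights(n_frames, peak = 0.25 * n_frames),
    lactate     = bolus_weights(n_frames, peak = 0.5 * n_frames),
    bicarbonate = bolus_weights(n_frames, peak = 0.6 * n_frames),
    # PET tracers: slow build to a plateau
    {
      w <- pmin(seq_len(n_frames) / (0.3 * n_frames), 1)
      w / sum(w)
    })
}

#' Ellipsoidal brain mask and cortical shell
#'
#' The synthetic "brain" is an axis-aligned ellipsoid centred on the grid,
#' sized to cover ~40% of the voxels; the "cortex" analog is the outer 30%
#' radial band of that ellipsoid, which maps cleanly onto the unit sphere for
#' the spin test.
#'
#' @param grid_shape integer triple.
#' @return `ellipsoid_mask()` returns a logical 3D array;
#'   `ellipsoid_radius()` the normalized radius field (1 at the mask surface).
#' @export
ellipsoid_mask <- function(grid_shape) {
  ellipsoid_radius(grid_shape) <= 1
}

#' @rdname ellipsoid_mask
#' @export
ellipsoid_radius <- function(grid_shape) {
  d <- as.integer(grid_shape)
  ctr <- (d + 1) / 2
  f <- (0.4 * 6 / pi)^(1 / 3)          # semi-axis fraction giving ~40% volume
  ax <- f * d / 2
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  r <- sqrt(((g$i - ctr[1]) / ax[1])^2 + ((g$j - ctr[2]) / ax[2])^2 +
            ((g$k - ctr[3]) / ax[3])^2)
  array(r, d)
}

#' Generate spatially autocorrelated latent fields
#'
#' Draws `n_latents` independent white Gaussian fields, smooths each to the
#' requested FWHM, and z-scores within the ellipsoidal brain mask (mean 0,
#' SD 1). Deterministic given the spec's seed.
#'
#' @param spec a [latent_field_spec()].
#' @return list with `fields` (list of [volume_map()]), `mask` (logical
#'   array), and `spec`.
#' @export
generate_latent_fields <- function(spec) {
  stopifnot(inherits(spec, "latent_field_spec"))
  d <- spec$grid_shape
  mask <- ellipsoid_mask(d)
  sigma_vox <- spec$smooth_fwhm_mm / (2 * sqrt(2 * log(2))) / spec$voxel_size_mm
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old), add = TRUE)
  fields <- lapply(seq_len(spec$n_latents), function(l) {
    f <- smooth3d_raw(array(stats::rnorm(prod(d)), d), sigma_vox)
    v <- f[mask]
    f <- (f - mean(v)) / stats::sd(v)
    volume_map(f, spec$voxel_size_mm)
  })
  list(fields = fields, mask = mask, spec = spec)
}

# nonnegativity shift: within-mask minimum becomes 0.1 x within-mask range
shift_nonneg <- function(a, mask) {
  v <- a[mask]
  rng <- diff(range(v))
  if (rng == 0) rng <- abs(v[1L]) + 1
  a - min(v) + 0.1 * rng
}

#' Generate one subject's multi-channel dynamic dataset
#'
#' Each channel's static map is a nonnegativity-shifted linear mix of the
#' latent fields, multiplied by a subject- and channel-specific lognormal
#' gain and perturbed with additive voxel noise (negative values clamped to
#' zero so frames stay nonnegative). Frames are the static map scaled by the
#' channel's time-course weights, which sum to 1, so the all-frame sum image
#' reproduces the static map exactly in the noiseless case.
#'
#' @param latents result of [generate_latent_fields()].
#' @param mixing a [mixing_spec()].
#' @param dyn a [dynamic_spec()].
#' @param subject_seed integer seed for this subject's gains and noise.
#' @return named list of [dynamic_series()], one per channel (hp channels
#'   first), with attribute `"static"` holding the noiseless-time static maps.
#' @export
generate_subject_dataset <- function(latents, mixing, dyn, subject_seed) {
  M <- rbind(mixing$mixing_hp, mixing$mixing_pet)
  if (ncol(M) != length(latents$fields))
    stop("mixing latent count does not match generated latents")
  mask <- latents$mask
  d <- dim(mask)
  L <- vapply(latents$fields, function(f) as.vector(f$values),
              numeric(prod(d)))
  vox <- spec_voxel(latents)
  old <- local_seed(subject_seed)
  on.exit(restore_seed(old), add = TRUE)
  channels <- rownames(M)
  out <- vector("list", length(channels))
  names(out) <- channels
  statics <- out
  times <- (seq_len(dyn$n_frames) - 1L) * dyn$frame_interval_s
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    static <- array(L %*% M[ci, ], d)
    static <- shift_nonneg(static, mask)
    gain <- stats::rlnorm(1L, meanlog = 0, sdlog = mixing$subject_noise_sd)
    static <- static * gain
    if (mixing$voxel_noise_sd > 0) {
      s <- stats::sd(static[mask])
      static <- static + array(stats::rnorm(prod(d),
                                            sd = mixing$voxel_noise_sd * s), d)
      static[static < 0] <- 0
    }
    w <- dyn$timecourse_shape[[ch]]
    if (is.null(w)) w <- default_timecourse(ch, dyn$n_frames)
    frames <- lapply(w, function(wt) volume_map(static * wt, vox))
    out[[ci]] <- dynamic_series(frames, times)
    statics[[ci]] <- volume_map(static, vox)
  }
  attr(out, "static") <- statics
  out
}

spec_voxel <- function(latents) latents$spec$voxel_size_mm

# Fibonacci lattice: n nearly uniform points on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Spherical parcellation of the cortical shell
#'
#' Places `n_parcels` centroids on the unit sphere with a Fibonacci lattice
#' (randomly rotated, seed-controlled), then labels every cortical-shell
#' voxel with the nearest centroid after radially projecting the voxel onto
#' the sphere. The shell is the outer 30% radial band of the ellipsoidal
#' mask. If a rotation leaves some parcel empty on the discrete grid, further
#' seed-derived rotations are tried (then the unrotated lattice) before
#' giving up.
#'
#' @param grid_shape integer triple (the mask's grid).
#' @param mask logical array from [ellipsoid_mask()] (or compatible).
#' @param n_parcels number of parcels (default 200, the atlas size the
#'   workflow targets).
#' @param seed integer seed for the lattice rotation.
#' @param shell_inner inner edge of the shell in normalized radius
#'   (default 0.7).
#' @return a [parcellation()] with labels 1..n_parcels on the shell and 0
#'   elsewhere.
#' @export
generate_spherical_parcellation <- function(grid_shape, mask,
                                            n_parcels = 200L, seed = 1L,
                                            shell_inner = 0.7) {
  r <- ellipsoid_radius(grid_shape)
  shell <- mask & r > shell_inner
  nshell <- sum(shell)
  if (nshell == 0L) stop("empty cortical shell")
  if (n_parcels > nshell)
    stop("n_parcels exceeds the number of shell voxels (", nshell, ")")
  d <- as.integer(grid_shape)
  ctr <- (d + 1) / 2
  f <- (0.4 * 6 / pi)^(1 / 3)
  ax <- f * d / 2
  idx <- which(shell, arr.ind = TRUE)
  u <- cbind((idx[, 1] - ctr[1]) / ax[1],
             (idx[, 2] - ctr[2]) / ax[2],
             (idx[, 3] - ctr[3]) / ax[3])
  u <- u / sqrt(rowSums(u^2))          # radial projection to the sphere
  base <- fibonacci_sphere(n_parcels)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  cand <- c(lapply(1:20, function(i) base %*% t(random_rotation())),
            list(base))
  for (C in cand) {
    lab_shell <- max.col(u %*% t(C), ties.method = "first")
    if (length(unique(lab_shell)) == n_parcels) {
      labels <- array(0L, d)
      labels[shell] <- lab_shell
      return(parcellation(labels, C, parcel_ids = seq_len(n_parcels)))
    }
  }
  stop("could not place ", n_parcels, " nonempty parcels on the shell; ",
       "reduce n_parcels")
}

#' Simulate a full multi-subject study
#'
#' Convenience wrapper tying the pieces together: latent fields, per-subject
#' dynamic datasets for every hyperpolarized and PET channel, the ellipsoidal
#' mask, and a spherical parcellation. Everything is a pure function of the
#' specs and the seed.
#'
#' @param field_spec a [latent_field_spec()]; its seed is derived from `seed`
#'   when omitted.
#' @param mixing a [mixing_spec()].
#' @param dyn a [dynamic_spec()].
#' @param n_parcels parcel count for the spherical parcellation.
#' @param seed master seed; subject seeds are `seed * 1000 + subject index`.
#' @return list with `subjects` (list of per-channel [dynamic_series()]
#'   lists), `static` (per-subject noiseless static maps), `latents`, `mask`,
#'   `parc`, and the specs.
#' @export
simulate_study <- function(field_spec = NULL, mixing = mixing_spec(),
                           dyn = dynamic_spec(), n_parcels = 200L,
                           seed = 1L) {
  if (is.null(field_spec))
    field_spec <- latent_field_spec(seed = seed)
  latents <- generate_latent_fields(field_spec)
  parc <- generate_spherical_parcellation(field_spec$grid_shape,
                                          latents$mask, n_parcels,
                                          seed = seed)
  subjects <- vector("list", mixing$n_subjects)
  statics <- vector("list", mixing$n_subjects)
  for (s in seq_len(mixing$n_subjects)) {
    ds <- generate_subject_dataset(latents, mixing, dyn,
                                   subject_seed = seed * 1000L + s)
    statics[[s]] <- attr(ds, "static")
    attr(ds, "static") <- NULL
    subjects[[s]] <- ds
  }
  list(subjects = subjects, static = statics, latents = latents,
       mask = latents$mask, parc = parc,
       field_spec = field_spec, mixing = mixing, dyn = dyn, seed = seed)
}

#' Write a simulated study to disk
#'
#' Writes one 4D NIfTI per subject and channel, the brain mask and
#' parcellation label volumes as 3D NIfTI, and the centroid table as CSV
#' (`parcel_id,x,y,z`).
#'
#' @param study result of [simulate_study()].
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vox <- study$field_spec$voxel_size_mm
  write_nifti(study$mask * 1, file.path(out_dir, "mask.nii.gz"), vox)
  write_nifti(study$parc$labels, file.path(out_dir, "parcellation.nii.gz"),
              vox)
  write_centroids_csv(study$parc, file.path(out_dir, "centroids.csv"))
  for (s in seq_along(study$subjects)) {
    for (ch in names(study$subjects[[s]])) {
      ser <- study$subjects[[s]][[ch]]
      arr4 <- array(unlist(lapply(ser$frames, function(f) f$values)),
                    c(dim(ser$frames[[1]]$values), length(ser$frames)))
      write_nifti(arr4, file.path(out_dir,
                                  sprintf("sub-%02d_%s.nii.gz", s, ch)),
                  vox, frame_interval_s = diff(ser$frame_times_s[1:2]))
    }
  }
  invisible(out_dir)
}
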