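# latent fields, subject datasets, spherical parcellation

test_that("generate_latent_fields is deterministic and z-scored", {
  spec <- latent_field_spec(grid_shape = c(16L, 16L, 16L), seed = 5)
  a <- generate_latent_fields(spec)
  b <- generate_latent_fields(spec)
  expect_identical(a$fields[[1]]$values, b$fields[[1]]$values)
  expect_identical(a$fields[[2]]$values, b$fields[[2]]$values)
  for (f in a$fields) {
    expect_equal(mean(f$values[a$mask]), 0, tolerance = 1e-10)
    expect_equal(sd(f$values[a$mask]), 1, tolerance = 1e-10)
    expect_true(all(is.finite(f$values)))
  }
  expect_error(latent_field_spec(grid_shape = c(4L, 16L, 16L)), ">= 8")
  expect_error(latent_field_spec(n_latents = 1L), "n_latents")
})

test_that("smooth_fwhm_mm = 0 gives white fields, > 0 autocorrelated", {
  lag1 <- function(v) {
    a <- v[-dim(v)[1], , ]; b <- v[-1, , ]
    cor(as.vector(a), as.vector(b))
  }
  white <- generate_latent_fields(latent_field_spec(smooth_fwhm_mm = 0,
                                                    seed = 8))
  expect_lt(abs(lag1(white$fields[[1]]$values)), 0.05)
  smooth <- generate_latent_fields(latent_field_spec(seed = 8))
  expect_gt(lag1(smooth$fields[[1]]$values), 0.5)
})

test_that("mask covers ~40% of the grid and shell is nonempty", {
  mask <- ellipsoid_mask(c(32L, 32L, 32L))
  expect_gt(mean(mask), 0.35)
  expect_lt(mean(mask), 0.45)
  r <- ellipsoid_radius(c(32L, 32L, 32L))
  expect_gt(sum(mask & r > 0.7), 1000)
})

test_that("subject datasets obey the mixing construction", {
  lf <- generate_latent_fields(latent_field_spec(
    grid_shape = c(16L, 16L, 16L), seed = 2))
  noiseless <- mixing_spec(subject_noise_sd = 0, voxel_noise_sd = 0,
                           n_subjects = 3L)
  d1 <- generate_subject_dataset(lf, noiseless, dynamic_spec(), 101)
  d2 <- generate_subject_dataset(lf, noiseless, dynamic_spec(), 202)
  # no subject noise: all subjects identical
  expect_equal(sum_image(d1$lactate)$values, sum_image(d2$lactate)$values)
  # frames sum back to the static map (time-course weights sum to 1)
  st <- attr(d1, "static")
  expect_equal(sum_image(d1$pyruvate)$values, st$pyruvate$values,
               tolerance = 1e-12)
  # all frame values nonnegative
  expect_true(all(vapply(d1$cmrglc$frames,
                         function(f) all(f$values >= 0), logical(1))))
  # determinism in subject_seed
  expect_identical(
    sum_image(generate_subject_dataset(lf, mixing_spec(n_subjects = 3L),
                                       dynamic_spec(), 7)$cbv)$values,
    sum_image(generate_subject_dataset(lf, mixing_spec(n_subjects = 3L),
                                       dynamic_spec(), 7)$cbv)$values)
  expect_error(generate_subject_dataset(
    lf, mixing_spec(mixing_hp = matrix(1, 3, 2),
                    mixing_pet = matrix(1, 4, 2), n_subjects = 3L),
    dynamic_spec(), 1), "latent count")
})

test_that("pure vascular loading makes pyruvate and cbv rank-identical", {
  lf <- generate_latent_fields(latent_field_spec(
    grid_shape = c(16L, 16L, 16L), seed = 6))
  mh <- matrix(0, 3, 3, dimnames = list(c("pyruvate", "lactate",
                                          "bicarbonate"), NULL))
  mp <- matrix(0, 4, 3, dimnames = list(c("cmrglc", "cbf", "cmro2", "cbv"),
                                        NULL))
  mh["pyruvate", 2] <- 1; mh["lactate", 1] <- 1; mh["bicarbonate", 1] <- 1
  mp["cbv", 2] <- 1; mp["cmrglc", 1] <- 1; mp["cbf", 1] <- 1
  mp["cmro2", 1] <- 1
  mix <- mixing_spec(mixing_hp = mh, mixing_pet = mp,
                     subject_noise_sd = 0, voxel_noise_sd = 0,
                     n_subjects = 3L)
  ds <- generate_subject_dataset(lf, mix, dynamic_spec(), 31)
  rho <- spearman_rho(sum_image(ds$pyruvate)$values[lf$mask],
                      sum_image(ds$cbv)$values[lf$mask])
  expect_equal(rho, 1)
})

test_that("spherical parcellation produces the requested nonempty parcels", {
  mask <- ellipsoid_mask(c(32L, 32L, 32L))
  p <- generate_spherical_parcellation(c(32L, 32L, 32L), mask, 200L,
                                       seed = 4)
  labs <- p$labels[p$labels > 0]
  expect_identical(sort(unique(labs)), 1:200)
  expect_equal(sqrt(rowSums(p$centroids^2)), rep(1, 200), tolerance = 1e-12)
  # labels only on the shell, never outside the mask
  expect_true(all(mask[p$labels > 0]))
  expect_error(generate_spherical_parcellation(c(32L, 32L, 32L), mask,
                                               100000L),
               "exceeds")
})

test_that("two parcels split the shell into nearest-centroid caps", {
  d <- c(16L, 16L, 16L)
  mask <- ellipsoid_mask(d)
  p <- generate_spherical_parcellation(d, mask, 2L, seed = 9)
  # brute force: every labeled voxel must sit closest to its own centroid
  r <- ellipsoid_radius(d)
  idx <- which(p$labels > 0, arr.ind = TRUE)
  ctr <- (d + 1) / 2
  ax <- (0.4 * 6 / pi)^(1 / 3) * d / 2
  u <- cbind((idx[, 1] - ctr[1]) / ax[1], (idx[, 2] - ctr[2]) / ax[2],
             (idx[, 3] - ctr[3]) / ax[3])
  u <- u / sqrt(rowSums(u^2))
  nearest <- apply(u %*% t(p$centroids), 1, which.max)
  expect_equal(unname(nearest), as.vector(p$labels[p$labels > 0]))
})

test_that("simulate_study is a pure function of its seed", {
  mix <- mixing_spec(n_subjects = 3L)
  fs <- latent_field_spec(grid_shape = c(16L, 16L, 16L), seed = 1)
  s1 <- simulate_study(fs, mix, n_parcels = 50L, seed = 12)
  s2 <- simulate_study(fs, mix, n_parcels = 50L, seed = 12)
  expect_identical(sum_image(s1$subjects[[2]]$cmro2)$values,
                   sum_image(s2$subjects[[2]]$cmro2)$values)
  expect_identical(s1$parc$labels, s2$parc$labels)
})

test_that("write_study round-trips through NIfTI and CSV", {
  dir <- withr::local_tempdir()
  mix <- mixing_spec(n_subjects = 3L)
  fs <- latent_field_spec(grid_shape = c(12L, 12L, 12L), seed = 3)
  study <- simulate_study(fs, mix, n_parcels = 20L, seed = 3)
  write_study(study, dir)
  mask <- read_nifti(file.path(dir, "mask.nii.gz"))
  expect_equal(mask$values > 0, study$mask)
  nii <- read_nifti(file.path(dir, "sub-01_pyruvate.nii.gz"))
  expect_equal(dim(nii$values), c(12L, 12L, 12L, 12L))
  expect_equal(nii$values[, , , 3],
               study$subjects[[1]]$pyruvate$frames[[3]]$values,
               tolerance = 1e-6)
  cent <- read_centroids_csv(file.path(dir, "centroids.csv"))
  expect_equal(unname(cent), unname(study$parc$centroids),
               tolerance = 1e-12)
})
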