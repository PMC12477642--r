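# sum images, normalization, group medians, smoothing, FWHM selection

test_that("detect_uptake_start finds the first real increase", {
  g <- tiny_grid()
  # frame means [1,1,5,9,9]: threshold = 1 + 0.05*(9-1) = 1.4 -> t = 10
  ser <- const_series(c(1, 1, 5, 9, 9), times = c(0, 5, 10, 15, 20))
  expect_equal(detect_uptake_start(ser, g$mask), 10)
  # monotone increase from the second frame
  ser2 <- const_series(c(1, 5, 6, 7))
  expect_equal(detect_uptake_start(ser2, g$mask), 5)
  expect_error(detect_uptake_start(const_series(c(2, 2, 2, 2)), g$mask),
               "no uptake")
  expect_error(detect_uptake_start(const_series(c(1, 2)), g$mask),
               "3 frames")
})

test_that("sum_image honors the three window modes", {
  g <- tiny_grid()
  ser <- const_series(rep(3, 12))
  expect_equal(sum_image(ser)$values, array(36, g$d))

  # frames at t = 0..55 step 5; [10, 30) keeps t in {10,15,20,25}
  ser2 <- const_series(1:12, times = seq(0, 55, by = 5))
  w <- integration_window("fixed_window", start_s = 10, duration_s = 20)
  expect_equal(sum_image(ser2, w)$values[1],
               sum(which(seq(0, 55, 5) %in% c(10, 15, 20, 25))))

  # last 20 min of a 60-min series keeps t >= 40 min
  times_min <- seq(0, 60, by = 5)
  ser3 <- const_series(seq_along(times_min), times = times_min * 60)
  w3 <- integration_window("last_minutes", tail_min = 20)
  expect_equal(sum_image(ser3, w3)$values[1],
               sum(which(times_min >= 40)))

  expect_error(sum_image(ser2, integration_window("fixed_window",
                                                  start_s = 1000,
                                                  duration_s = 5)),
               "no frames")
})

test_that("sum_image is additive over disjoint windows", {
  ser <- const_series(runif(12, 1, 2), times = seq(0, 55, by = 5))
  w1 <- integration_window("fixed_window", start_s = 0, duration_s = 30)
  w2 <- integration_window("fixed_window", start_s = 30, duration_s = 30)
  expect_equal(sum_image(ser, w1)$values + sum_image(ser, w2)$values,
               sum_image(ser)$values)
})

test_that("normalize_global_mean gives mean 1, zeros outside, idempotent", {
  g <- tiny_grid()
  v <- array(0, g$d)
  v[g$mask] <- rep(c(2, 4), length.out = sum(g$mask))
  m <- normalize_global_mean(volume_map(v, g$vox), g$mask)
  expect_equal(sort(unique(m$values[g$mask])), c(2 / 3, 4 / 3))
  expect_true(all(m$values[!g$mask] == 0))

  r <- rand_map(g$d, seed = 2, positive = TRUE)
  n1 <- normalize_global_mean(r, g$mask)
  expect_equal(mean(n1$values[g$mask]), 1, tolerance = 1e-12)
  # idempotence and scale invariance
  expect_equal(normalize_global_mean(n1, g$mask)$values, n1$values)
  scaled <- volume_map(r$values * 37.5, r$voxel_size_mm)
  expect_equal(normalize_global_mean(scaled, g$mask)$values, n1$values)
  neg <- volume_map(array(-1, g$d), g$vox)
  expect_error(normalize_global_mean(neg, g$mask), "positive")
})

test_that("group_median matches sort-based oracle and is permutation-invariant", {
  g <- tiny_grid(c(8L, 8L, 8L))
  maps <- lapply(1:5, function(s) rand_map(g$d, seed = s))
  gm <- group_median(maps)
  stack <- sapply(maps, function(m) as.vector(m$values))
  oracle <- apply(stack, 1, function(v) {
    s <- sort(v); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else mean(s[n / 2 + 0:1])
  })
  expect_equal(as.vector(gm$values), oracle)
  # even count: {1,3} -> 2 at every voxel
  ev <- group_median(list(volume_map(array(1, g$d), 6),
                          volume_map(array(3, g$d), 6)))
  expect_equal(ev$values, array(2, g$d))
  # permutation invariance and single-map identity
  expect_equal(group_median(maps[c(4, 1, 5, 3, 2)])$values, gm$values)
  expect_equal(group_median(maps[1])$values, maps[[1]]$values)
  expect_error(group_median(list(maps[[1]],
                                 volume_map(array(0, c(4, 4, 4)), 6))),
               "grid")
})

test_that("gaussian_smooth matches the brute-force masked convolution", {
  g <- tiny_grid(c(8L, 8L, 8L))
  m <- rand_map(g$d, seed = 4)
  sm <- gaussian_smooth(m, 14, g$mask)
  brute <- brute_smooth(m$values, 14, g$mask, g$vox)
  expect_equal(sm$values[g$mask], brute[g$mask], tolerance = 1e-10)
  expect_true(all(sm$values[!g$mask] == 0))
})

test_that("gaussian_smooth preserves constants, identity at fwhm 0", {
  g <- tiny_grid()
  const <- volume_map(array(5, g$d), g$vox)
  expect_equal(gaussian_smooth(const, 14, g$mask)$values[g$mask],
               rep(5, sum(g$mask)), tolerance = 1e-12)
  m <- rand_map(g$d, seed = 5)
  expect_identical(gaussian_smooth(m, 0, g$mask)$values, m$values)
  expect_error(gaussian_smooth(m, -1, g$mask), "nonnegative")
  # general maps: within-mask mean moves by < 1% at default settings
  mp <- rand_map(g$d, seed = 6, positive = TRUE)
  mu0 <- mean(mp$values[g$mask])
  mu1 <- mean(gaussian_smooth(mp, 14, g$mask)$values[g$mask])
  expect_lt(abs(mu1 - mu0) / mu0, 0.01)
})

test_that("optimize_fwhm recovers a planted smoothing scale", {
  lf <- generate_latent_fields(latent_field_spec(
    grid_shape = c(16L, 16L, 16L), n_latents = 3L, seed = 11))
  mask <- lf$mask
  set.seed(42)
  maps_a <- lapply(lf$fields, gaussian_smooth, fwhm_mm = 10, mask = mask)
  maps_b <- lapply(lf$fields, function(f) {
    v <- f$values + array(rnorm(length(f$values), sd = 0.02), dim(f$values))
    volume_map(v, f$voxel_size_mm)
  })
  expect_equal(optimize_fwhm(maps_a, maps_b, mask, c(0, 5, 10, 20)), 10)
  # a perfect rank match can only be perturbed by smoothing
  expect_equal(optimize_fwhm(lf$fields, lf$fields, mask, c(0, 5)), 0)
  expect_equal(optimize_fwhm(lf$fields, lf$fields, mask, 7), 7)
  expect_error(optimize_fwhm(list(), list(), mask, c(0, 5)), "nonempty")
})
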