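#' Spatial-regression residual maps
#'
#' Regresses one map on another across within-mask voxels (ordinary least
#' squares with intercept) and returns the residual map. This is the common
#' core of the glycolytic index (CMRglc on CMRO2) and the hyperpolarized
#' residual images: lactate-bicarbonate (LBR), lactate-pyruvate (LPR) and
#' bicarbonate-pyruvate (BPR). Residuals have within-mask mean 0 by
#' construction and are orthogonal to the regressor, which is why the
#' workflow prefers them to noisy voxelwise ratios.
#'
#' @param dependent,independent [volume_map()] objects on one grid.
#' @param mask logical 3D array; the independent map must have nonzero
#'   variance within it.
#' @param dependent_label,independent_label channel names recorded in the
#'   result.
#' @return object of class `"residual_map"`: list with `map` (a
#'   [volume_map()], zero outside the mask), `slope`, `intercept`,
#'   `dependent_label`, `independent_label`.
#' @export
spatial_regress_out <- function(dependent, independent, mask,
                                dependent_label = "dependent",
                                independent_label = "independent") {
  m <- check_mask(dependent, mask)
  if (!identical(dim(independent$values), dim(dependent$values)))
    stop("map grids differ")
  y <- dependent$values[m]
  x <- independent$values[m]
  vx <- stats::var(x)
  if (!is.finite(vx) || vx == 0)
    stop("independent map is constant within the mask")
  slope <- stats::cov(x, y) / vx
  intercept <- mean(y) - slope * mean(x)
  res <- array(0, dim(m))
  res[m] <- y - (intercept + slope * x)
  structure(list(map = volume_map(res, dependent$voxel_size_mm),
                 slope = slope, intercept = intercept,
                 dependent_label = dependent_label,
                 independent_label = independent_label),
            class = "residual_map")
}

#' @export
print.residual_map <- function(x, ...) {
  cat(sprintf("<residual_map> %s ~ %s: slope %.4g, intercept %.4g\n",
              x$dependent_label, x$independent_label, x$slope, x$intercept))
  invisible(x)
}

#' Glycolytic index
#'
#' Residuals of a whole-brain spatial regression of the glucose-consumption
#' map (CMRglc, dependent) on the oxygen-consumption map (CMRO2,
#' independent). The GI has whole-brain mean 0; positive values mark regions
#' where glucose use exceeds oxygen use relative to the rest of the brain —
#' a relative index of aerobic glycolysis.
#'
#' @param cmrglc,cmro2 [volume_map()] objects.
#' @inheritParams spatial_regress_out
#' @return a `"residual_map"`.
#' @export
compute_gi <- function(cmrglc, cmro2, mask) {
  spatial_regress_out(cmrglc, cmro2, mask,
                      dependent_label = "cmrglc",
                      independent_label = "cmro2")
}

#' Remove the vascular component from a map
#'
#' Regresses a sum image on the blood-volume (CBV) map and returns the
#' residual with the fitted intercept restored, so the corrected map remains
#' positive and usable in downstream ratios (the oxygen-extraction
#' fraction). The output is uncorrelated with CBV within the mask.
#'
#' @param map a [volume_map()] (e.g., the oxygen sum image).
#' @param cbv a nonconstant [volume_map()].
#' @inheritParams spatial_regress_out
#' @param restore_intercept add the fitted intercept back (default `TRUE`);
#'   `FALSE` gives the plain mean-0 residual.
#' @return a [volume_map()].
#' @export
remove_vascular_component <- function(map, cbv, mask,
                                      restore_intercept = TRUE) {
  r <- spatial_regress_out(map, cbv, mask,
                           dependent_label = "map",
                           independent_label = "cbv")
  out <- r$map$values
  m <- check_mask(map, mask)
  if (restore_intercept) out[m] <- out[m] + r$intercept
  volume_map(out, map$voxel_size_mm)
}

#' Oxygen extraction fraction map
#'
#' OEF is the voxelwise ratio of the vascular-corrected oxygen sum image to
#' the water (blood-flow) sum image, normalized to a within-mask mean of 1.
#' Voxels whose denominator falls below `denom_floor` times the within-mask
#' median of the water image are excluded from the mask before the division
#' to avoid amplifying noise.
#'
#' @param o2_sum,h2o_sum,cbv [volume_map()] objects.
#' @inheritParams spatial_regress_out
#' @param denom_floor denominator floor as a fraction of the within-mask
#'   median of `h2o_sum` (default 0.05).
#' @return list with `map` (a [volume_map()], mean 1 on the reduced mask)
#'   and `mask` (the reduced logical mask actually used).
#' @export
compute_oef <- function(o2_sum, h2o_sum, cbv, mask, denom_floor = 0.05) {
  m <- check_mask(o2_sum, mask)
  o2c <- remove_vascular_component(o2_sum, cbv, mask)
  floor_val <- denom_floor * stats::median(h2o_sum$values[m])
  if (!is.finite(floor_val) || floor_val <= 0)
    stop("denominator floor is nonpositive: h2o image unusable as a divisor")
  keep <- m & h2o_sum$values >= floor_val
  if (!any(keep))
    stop("all voxels fall below the denominator floor")
  ratio <- array(0, dim(m))
  ratio[keep] <- o2c$values[keep] / h2o_sum$values[keep]
  oef <- normalize_global_mean(volume_map(ratio, o2_sum$voxel_size_mm), keep)
  list(map = oef, mask = keep)
}
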