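#' Volumetric map and dynamic series containers
#'
#' A `volume_map` is a 3D scalar field on a fixed grid with an isotropic voxel
#' size in millimetres. A `dynamic_series` is an ordered set of frames on a
#' shared grid with strictly increasing frame times, the raw material for sum
#' images. Both are plain lists with a class attribute, in the style of base-R
#' modelling objects: light enough to build in tests, structured enough to
#' validate.
#'
#' @param values numeric 3D array.
#' @param voxel_size_mm positive scalar, isotropic voxel edge length.
#' @return `volume_map()` returns an object of class `"volume_map"`.
#' @examples
#' v <- volume_map(array(1, c(8, 8, 8)), voxel_size_mm = 6)
#' dim(v$values)
#' @export
volume_map <- function(values, voxel_size_mm) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      !is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("'voxel_size_mm' must be a positive scalar")
  structure(list(values = values, voxel_size_mm = voxel_size_mm),
            class = "volume_map")
}

#' @rdname volume_map
#' @param frames list of `volume_map` objects on identical grids.
#' @param frame_times_s strictly increasing nonnegative frame times (seconds).
#' @export
dynamic_series <- function(frames, frame_times_s) {
  if (length(frames) < 1L) stop("need at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "volume_map")))
    stop("all frames must be volume_map objects")
  if (length(frame_times_s) != length(frames))
    stop("one time per frame required")
  if (any(frame_times_s < 0) || any(diff(frame_times_s) <= 0))
    stop("frame times must be nonnegative and strictly increasing")
  d <- dim(frames[[1L]]$values)
  ok <- vapply(frames, function(f) identical(dim(f$values), d), logical(1))
  if (!all(ok)) stop("all frames must share one grid")
  structure(list(frames = frames, frame_times_s = as.numeric(frame_times_s)),
            class = "dynamic_series")
}

#' @export
print.volume_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_map> %d x %d x %d voxels, %.3g mm isotropic\n",
              d[1], d[2], d[3], x$voxel_size_mm))
  invisible(x)
}

#' @export
print.dynamic_series <- function(x, ...) {
  cat(sprintf("<dynamic_series> %d frames, t = %.4g..%.4g s\n",
              length(x$frames), min(x$frame_times_s), max(x$frame_times_s)))
  invisible(x)
}

# mask helpers ---------------------------------------------------------------

check_mask <- function(map, mask) {
  if (!is.array(mask) || !identical(dim(mask), dim(map$values)))
    stop("mask grid does not match map grid")
  m <- as.logical(mask)
  if (!any(m)) stop("mask is empty")
  array(m, dim(mask))
}

mask_values <- function(map, mask) map$values[check_mask(map, mask)]

mask_mean <- function(map, mask) mean(mask_values(map, mask))
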