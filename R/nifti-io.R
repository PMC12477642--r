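#' Minimal NIfTI-1 input/output
#'
#' Self-contained reader/writer for single-file NIfTI-1 (`.nii`, `.nii.gz`)
#' covering what this package needs: 3D and 4D volumes, datatypes uint8,
#' int16, int32, float32 and float64, scale slope/intercept on read, and an
#' axis-aligned affine built from the isotropic voxel size. No R NIfTI
#' package is assumed; the header layout follows the NIfTI-1.1 standard.
#'
#' @param path file path; `.gz` suffix selects gzip compression.
#' @return `read_nifti()` returns a list with `values` (3D or 4D array),
#'   `voxel_size_mm` (pixdim of the first spatial axis), and
#'   `frame_interval_s` (4D only, else `NA`).
#' @name nifti_io
NULL

nifti_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' @rdname nifti_io
#' @param values numeric 3D or 4D array.
#' @param voxel_size_mm isotropic voxel size written into pixdim and the
#'   sform rows.
#' @param frame_interval_s frame spacing for 4D data (pixdim\[5\]).
#' @param datatype one of `"float32"` (default) or `"float64"`.
#' @export
write_nifti <- function(values, path, voxel_size_mm = 1,
                        frame_interval_s = 0, datatype = c("float32",
                                                           "float64")) {
  datatype <- match.arg(datatype)
  d <- dim(values)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("'values' must be a 3D or 4D array")
  ndim <- length(d)
  dim8 <- c(ndim, d, rep(1L, 7L - length(d)))
  dtcode <- if (datatype == "float32") 16L else 64L
  bitpix <- if (datatype == "float32") 32L else 64L
  con <- nifti_con(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wc <- function(s, len) {
    raw_ <- charToRaw(s)
    writeBin(c(raw_, raw(len - length(raw_))), con)
  }
  wi(348L, 4L)                         # sizeof_hdr
  wc("", 10L); wc("", 18L)             # data_type, db_name
  wi(0L, 4L); wi(0L, 2L); wc("r", 1L); wc("", 1L)  # extents..dim_info
  wi(dim8, 2L)                         # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2L)           # intent_p1..3, intent_code
  wi(dtcode, 2L); wi(bitpix, 2L); wi(0L, 2L)       # datatype,bitpix,slice_start
  wf(c(1, rep(voxel_size_mm, 3L), frame_interval_s, 0, 0, 0))  # pixdim[8]
  wf(352); wf(1); wf(0)                # vox_offset, scl_slope, scl_inter
  wi(0L, 2L); wc("", 1L); wc("", 1L)   # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                    # cal_max, cal_min, slice_dur, toffset
  wi(c(0L, 0L), 4L)                    # glmax, glmin
  wc("crossmodal", 80L); wc("", 24L)   # descrip, aux_file
  wi(c(0L, 2L), 2L)                    # qform_code = 0, sform_code = 2
  wf(c(0, 0, 0, 0, 0, 0))              # quatern b,c,d + qoffset x,y,z
  wf(c(voxel_size_mm, 0, 0, 0))        # srow_x
  wf(c(0, voxel_size_mm, 0, 0))        # srow_y
  wf(c(0, 0, voxel_size_mm, 0))        # srow_z
  wc("", 16L)                          # intent_name
  wc("n+1", 4L)                        # magic (with trailing NUL)
  writeBin(raw(4L), con)               # no extensions
  writeBin(as.numeric(values), con, size = bitpix / 8L, endian = "little")
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_nifti <- function(path) {
  con <- nifti_con(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header")
  sz_le <- readBin(hdr[1:4], "integer", 1L, endian = "little")
  endian <- if (sz_le == 348L) "little" else "big"
  ri <- function(off, n, size)
    readBin(hdr[(off + 1):(off + n * size)], "integer", n, size = size,
            endian = endian)
  rf <- function(off, n)
    readBin(hdr[(off + 1):(off + n * 4)], "numeric", n, size = 4L,
            endian = endian)
  if (ri(0L, 1L, 4L) != 348L) stop("not a NIfTI-1 file")
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic: ", magic)
  dim8 <- ri(40L, 8L, 2L)
  ndim <- dim8[1L]
  if (!(ndim %in% c(3L, 4L))) stop("only 3D/4D NIfTI supported")
  d <- dim8[2:(1 + ndim)]
  dtcode <- ri(70L, 1L, 2L)
  pixdim <- rf(76L, 8L)
  vox_offset <- rf(108L, 1L)
  slope <- rf(112L, 1L); inter <- rf(116L, 1L)
  spec <- switch(as.character(dtcode),
    "2"  = list(what = "integer", size = 1L, signed = FALSE),
    "4"  = list(what = "integer", size = 2L, signed = TRUE),
    "8"  = list(what = "integer", size = 4L, signed = TRUE),
    "16" = list(what = "numeric", size = 4L, signed = TRUE),
    "64" = list(what = "numeric", size = 8L, signed = TRUE),
    stop("unsupported NIfTI datatype code: ", dtcode))
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(d)
  x <- readBin(con, spec$what, n, size = spec$size, signed = spec$signed,
               endian = endian)
  if (length(x) != n) stop("truncated NIfTI data section")
  if (slope != 0 && !(slope == 1 && inter == 0)) x <- x * slope + inter
  list(values = array(as.numeric(x), d),
       voxel_size_mm = pixdim[2L],
       frame_interval_s = if (ndim == 4L) pixdim[5L] else NA_real_)
}
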