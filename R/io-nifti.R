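# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer for 3-D
# scalar volumes.  No NIfTI package ships with the target environment, so
# the 348-byte header is handled directly.  Data are written as float64
# (datatype 64) with the affine stored in the sform rows (sform_code 2);
# reading supports the common scalar datatypes and qform fallback.

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a scalar volume as NIfTI-1
#'
#' @param volume a [scalar_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path) {
  if (!inherits(volume, "scalar_volume"))
    abort("volume must be a scalar_volume", "tractsa_volume_error")
  d <- dim(volume$data)
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_i32(348)                              # sizeof_hdr
  w_raw(36)                               # data_type..dim_info
  w_i16(c(3, d, 1, 1, 1, 1))              # dim[8]
  w_f32(c(0, 0, 0))                       # intent_p1..p3
  w_i16(0)                                # intent_code
  w_i16(64)                               # datatype = float64
  w_i16(64)                               # bitpix
  w_i16(0)                                # slice_start
  w_f32(c(1, volume$voxel_size, 1, 1, 1, 1))  # pixdim[8] (qfac = 1)
  w_f32(352)                              # vox_offset
  w_f32(c(1, 0))                          # scl_slope, scl_inter
  w_i16(0); w_raw(1); w_raw(1)            # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0))                       # cal_max, cal_min, slice_duration
  w_f32(0)                                # toffset
  w_i32(c(0, 0))                          # glmax, glmin
  w_raw(80); w_raw(24)                    # descrip, aux_file
  w_i16(0)                                # qform_code
  w_i16(2)                                # sform_code = aligned/atlas
  w_f32(c(0, 0, 0, 0, 0, 0))              # quatern_b..qoffset_z
  w_f32(volume$affine[1, ])               # srow_x
  w_f32(volume$affine[2, ])               # srow_y
  w_f32(volume$affine[3, ])               # srow_z
  w_raw(16)                               # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  w_raw(4)                                # extension flag (none)
  writeBin(as.numeric(volume$data), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 scalar volume
#'
#' Supports uncompressed and gzipped single-file NIfTI-1 with datatypes
#' uint8, int16, int32, float32 and float64; applies `scl_slope`/
#' `scl_inter` when set.  The affine comes from the sform when
#' `sform_code > 0`, else from the qform quaternion, else from `pixdim`.
#' 4-D files with a single volume are squeezed to 3-D.
#'
#' @param path file path.
#' @return a [scalar_volume()].
#' @export
read_nifti <- function(path) {
  if (!file.exists(path))
    abort(sprintf("no such file: %s", path), "tractsa_io_error")
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348)
    abort(sprintf("%s: truncated NIfTI header (%d bytes)", path, length(hdr)),
          "tractsa_nifti_error")
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
  if (sz != 348) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
    if (sz != 348)
      abort(sprintf("%s: bad sizeof_hdr (not NIfTI-1)", path),
            "tractsa_nifti_error")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    abort(sprintf("%s: bad magic '%s'", path, magic), "tractsa_nifti_error")
  i16 <- function(off, n = 1) readBin(hdr[(off + 1):(off + 2 * n)], "integer",
                                      n = n, size = 2, endian = endian)
  f32 <- function(off, n = 1) readBin(hdr[(off + 1):(off + 4 * n)], "double",
                                      n = n, size = 4, endian = endian)
  dim8 <- i16(40, 8)
  nd <- dim8[1]
  if (!nd %in% c(3, 4) || (nd == 4 && dim8[5] != 1))
    abort(sprintf("%s: only 3-D volumes supported (dim = %s)", path,
                  paste(dim8[2:(nd + 1)], collapse = "x")),
          "tractsa_nifti_error")
  d <- dim8[2:4]
  datatype <- i16(70)
  pixdim <- f32(76, 8)
  vox_offset <- f32(108)
  scl_slope <- f32(112); scl_inter <- f32(116)
  qform_code <- i16(252); sform_code <- i16(254)
  spec <- switch(as.character(datatype),
                 "2" = list(what = "integer", size = 1, signed = FALSE),
                 "4" = list(what = "integer", size = 2, signed = TRUE),
                 "8" = list(what = "integer", size = 4, signed = TRUE),
                 "16" = list(what = "double", size = 4, signed = TRUE),
                 "64" = list(what = "double", size = 8, signed = TRUE),
                 abort(sprintf("%s: unsupported datatype %d", path, datatype),
                       "tractsa_nifti_error"))
  skip <- round(vox_offset) - 348L  # gz connections cannot seek
  if (skip > 0) invisible(readBin(con, "raw", n = skip))
  nvox <- prod(d)
  dat <- readBin(con, spec$what, n = nvox, size = spec$size,
                 signed = spec$signed, endian = endian)
  if (length(dat) < nvox)
    abort(sprintf("%s: data truncated (%d of %d voxels)", path,
                  length(dat), nvox), "tractsa_nifti_error")
  dat <- as.numeric(dat)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    dat <- dat * scl_slope + scl_inter
  if (sform_code > 0) {
    affine <- rbind(f32(280, 4), f32(296, 4), f32(312, 4), c(0, 0, 0, 1))
  } else if (qform_code > 0) {
    b <- f32(256); c_ <- f32(260); dq <- f32(264)
    a <- sqrt(max(0, 1 - b^2 - c_^2 - dq^2))
    qfac <- if (pixdim[1] < 0) -1 else 1
    R <- matrix(c(
      a * a + b * b - c_ * c_ - dq * dq, 2 * (b * c_ - a * dq), 2 * (b * dq + a * c_),
      2 * (b * c_ + a * dq), a * a + c_ * c_ - b * b - dq * dq, 2 * (c_ * dq - a * b),
      2 * (b * dq - a * c_), 2 * (c_ * dq + a * b), a * a + dq * dq - b * b - c_ * c_),
      3, 3, byrow = TRUE)
    S <- R %*% diag(c(pixdim[2], pixdim[3], qfac * pixdim[4]))
    affine <- rbind(cbind(S, f32(268, 3)), c(0, 0, 0, 1))
  } else {
    affine <- rbind(cbind(diag(pixdim[2:4]), c(0, 0, 0)), c(0, 0, 0, 1))
  }
  scalar_volume(array(dat, dim = d), affine = affine,
                voxel_size = abs(pixdim[2:4]))
}
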