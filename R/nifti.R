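# Minimal NIfTI-1 reader/writer.
#
# No NIfTI package is assumed; the format's single-file variant (.nii /
# .nii.gz) is implemented directly: the 348-byte header, the 4-byte
# extension flag and the voxel data, little-endian. Supported on read:
# uint8, int16, int32, float32, float64 with scl_slope/scl_inter scaling
# and the sform affine; on write: float32 (default, single precision on
# disk), float64 and int32. Cross-checked against nibabel in the test
# suite.

nifti_datatypes <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE))

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

pad_raw <- function(txt, len) {
  r <- charToRaw(txt)
  if (length(r) > len) r <- r[seq_len(len)]
  c(r, raw(len - length(r)))
}

#' Write a volume as NIfTI-1
#'
#' @param vol 3D or 4D numeric array. The slice axis is the third spatial
#'   axis.
#' @param path Output path; `.nii` or `.nii.gz`.
#' @param affine 4x4 voxel-to-world matrix stored as the sform (default:
#'   the `affine` attribute of `vol`, else `diag(c(pixdim, 1))`).
#' @param pixdim Voxel size (and time step for 4D), defaults to the
#'   `pixdim` attribute of `vol`, else 1s.
#' @param datatype One of `"float32"` (default), `"float64"`, `"int32"`.
#'
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, affine = NULL, pixdim = NULL,
                         datatype = c("float32", "float64", "int32")) {
  datatype <- match.arg(datatype)
  dt <- nifti_datatypes[[datatype]]
  nd <- length(dim(vol))
  if (nd < 3L || nd > 4L) stop("vol must be a 3D or 4D array")
  if (is.null(pixdim)) pixdim <- attr(vol, "pixdim")
  if (is.null(pixdim)) pixdim <- rep(1, nd)
  pixdim <- rep_len(as.numeric(pixdim), nd)
  if (is.null(affine)) affine <- attr(vol, "affine")
  if (is.null(affine)) affine <- diag(c(pixdim[1:3], 1))
  if (!identical(dim(affine), c(4L, 4L))) stop("affine must be 4x4")

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(x) writeBin(x, con)

  w_i32(348L)                                   # sizeof_hdr
  w_raw(raw(10L + 18L))                         # data_type, db_name
  w_i32(0L); w_i16(0L)                          # extents, session_error
  w_raw(c(charToRaw("r"), as.raw(0L)))          # regular, dim_info
  dims <- rep(1L, 8L); dims[1L] <- nd
  dims[seq_len(nd) + 1L] <- dim(vol)
  w_i16(dims)
  w_f32(c(0, 0, 0)); w_i16(0L)                  # intent_p1..3, intent_code
  w_i16(dt$code); w_i16(dt$bitpix); w_i16(0L)   # datatype, bitpix, slice_start
  pd <- rep(0, 8L); pd[1L] <- 1                 # qfac
  pd[seq_len(nd) + 1L] <- pixdim
  w_f32(pd)
  w_f32(352)                                    # vox_offset
  w_f32(1); w_f32(0)                            # scl_slope, scl_inter
  w_i16(0L); w_raw(as.raw(0L))                  # slice_end, slice_code
  w_raw(as.raw(10L))                            # xyzt_units: mm | sec
  w_f32(c(0, 0, 0, 0))                          # cal_max..toffset
  w_i32(c(0L, 0L))                              # glmax, glmin
  w_raw(pad_raw("vsaslkin", 80L))               # descrip
  w_raw(raw(24L))                               # aux_file
  w_i16(0L); w_i16(2L)                          # qform_code, sform_code
  w_f32(rep(0, 6L))                             # quatern, qoffset
  w_f32(affine[1L, ]); w_f32(affine[2L, ]); w_f32(affine[3L, ])
  w_raw(raw(16L))                               # intent_name
  w_raw(c(charToRaw("n+1"), as.raw(0L)))        # magic
  w_raw(raw(4L))                                # extension flag
  if (dt$what == "integer")
    writeBin(as.integer(round(vol)), con, size = dt$size, endian = "little")
  else
    writeBin(as.numeric(vol), con, size = dt$size, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#'
#' @return Numeric array (3D/4D) with attributes `affine` (4x4 sform, or
#'   pixdim-diagonal fallback), `pixdim`, and `datatype`. Values are scaled
#'   by `scl_slope` / `scl_inter` when present.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  r_i32 <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  r_i16 <- function(n) readBin(con, "integer", n, size = 2L, endian = "little")
  r_f32 <- function(n) readBin(con, "double", n, size = 4L, endian = "little")
  skip <- function(n) invisible(readBin(con, "raw", n))

  if (r_i32(1L) != 348L)
    stop("not a little-endian NIfTI-1 file (sizeof_hdr != 348): ", path)
  skip(36L)                                      # through dim_info
  dims <- r_i16(8L)
  nd <- dims[1L]
  if (nd < 3L || nd > 4L) stop("only 3D/4D volumes are supported")
  shape <- dims[seq_len(nd) + 1L]
  skip(14L)                                      # intent fields
  dcode <- r_i16(1L); skip(2L + 2L)              # bitpix, slice_start
  pd <- r_f32(8L)
  vox_offset <- r_f32(1L)
  scl_slope <- r_f32(1L); scl_inter <- r_f32(1L)
  skip(2L + 1L + 1L + 16L + 8L)                  # slice/cal/glmax/glmin
  skip(80L + 24L)                                # descrip, aux_file
  skip(2L); sform_code <- r_i16(1L)
  skip(24L)                                      # quatern + qoffset
  srow <- matrix(r_f32(12L), nrow = 3L, byrow = TRUE)
  skip(16L)
  magic <- rawToChar(readBin(con, "raw", 3L)); skip(1L)
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic in ", path)

  dt_name <- names(Filter(function(d) d$code == dcode, nifti_datatypes))
  if (length(dt_name) != 1L) stop("unsupported NIfTI datatype code ", dcode)
  dt <- nifti_datatypes[[dt_name]]
  skip(as.integer(vox_offset) - 348L)
  n <- prod(shape)
  data <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = "little")
  if (length(data) != n) stop("truncated NIfTI data in ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  vol <- array(as.numeric(data), shape)
  affine <- if (sform_code > 0L) rbind(srow, c(0, 0, 0, 1))
            else diag(c(pd[2:4], 1))
  attr(vol, "affine") <- affine
  attr(vol, "pixdim") <- pd[seq_len(nd) + 1L]
  attr(vol, "datatype") <- dt_name
  vol
}
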