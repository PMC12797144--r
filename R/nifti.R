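# Minimal NIfTI-1 reader/writer.
#
# The package reads and writes uncompressed or gzipped single-file .nii
# volumes directly with readBin/writeBin: 3D/4D images, datatypes uint8,
# int16, int32, float32, float64, scl_slope/scl_inter scaling, and the
# sform (or quaternion qform) affine. This is deliberately narrow -- enough
# for 4D timeseries, integer label masks, and scalar gradient maps -- and
# was cross-checked against nibabel during development.

nifti_dtypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L)
)

#' Read a NIfTI-1 image
#'
#' Supports single-file `.nii` and `.nii.gz`, little- or big-endian, with
#' the datatypes uint8/int16/int32/float32/float64. The affine is taken
#' from the sform when set, else reconstructed from the quaternion qform,
#' else a diagonal pixdim affine.
#'
#' @param path file path.
#' @return list with `data` (array with full image dimensions), `affine`
#'   (4 x 4), `pixdim`, `datatype`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  endian <- "little"
  if (sz != 348L) {
    sz_be <- readBin(packBits(intToBits(sz)), "integer", 1L, size = 4L,
                     endian = "big")
    if (sz_be == 348L) endian <- "big"
    else stop(path, " is not a NIfTI-1 file (sizeof_hdr = ", sz, ")",
              call. = FALSE)
  }
  readBin(con, "raw", 36L)                               # unused fields
  dim <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "raw", 12L)                               # intent_p1..p3
  readBin(con, "integer", 1L, size = 2L, endian = endian) # intent_code
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 2L, size = 2L, endian = endian) # bitpix, slice_start
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", 1L, size = 4L, endian = endian)
  readBin(con, "raw", 28L)                               # slice/cal/gl fields
  readBin(con, "raw", 104L)                              # descrip + aux_file
  qform_code <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  sform_code <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  quat <- readBin(con, "double", 6L, size = 4L, endian = endian)
  srow <- readBin(con, "double", 12L, size = 4L, endian = endian)
  readBin(con, "raw", 16L)                               # intent_name
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!startsWith(magic, "n+1") && !startsWith(magic, "ni1")) {
    stop(path, " has an unrecognized NIfTI magic string", call. = FALSE)
  }

  nd <- dim[1L]
  if (nd < 1L || nd > 7L) stop("invalid NIfTI ndim: ", nd, call. = FALSE)
  dims <- dim[2:(1 + nd)]
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype,
                        call. = FALSE)
  skip <- round(vox_offset) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data in ", path, call. = FALSE)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  data <- array(as.numeric(vals), dim = dims)

  affine <- if (sform_code > 0L) {
    rbind(matrix(srow, 3L, 4L, byrow = TRUE), c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    b <- quat[1]; c_ <- quat[2]; d <- quat[3]
    a2 <- 1 - b^2 - c_^2 - d^2
    a <- sqrt(max(a2, 0))
    R <- rbind(
      c(a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d), 2 * (b * d + a * c_)),
      c(2 * (b * c_ + a * d), a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b)),
      c(2 * (b * d - a * c_), 2 * (c_ * d + a * b), a^2 + d^2 - b^2 - c_^2))
    qfac <- if (pixdim[1] == -1) -1 else 1
    sc <- c(pixdim[2], pixdim[3], pixdim[4] * qfac)
    A <- R %*% diag(sc)
    rbind(cbind(A, quat[4:6]), c(0, 0, 0, 1))
  } else {
    A <- diag(4)
    diag(A)[1:3] <- ifelse(pixdim[2:4] > 0, pixdim[2:4], 1)
    A
  }
  list(data = data, affine = affine, pixdim = pixdim[2:4], datatype = datatype)
}

#' Write a NIfTI-1 image
#'
#' Writes a 3D or 4D array as a single-file little-endian `.nii` (gzipped
#' when the path ends in `.gz`), storing the affine in the sform
#' (`sform_code = 2`).
#'
#' @param data numeric/integer array, 3 or 4 dimensions.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param datatype `"float32"` (default), `"float64"`, `"int16"`, or
#'   `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4),
                        datatype = c("float32", "float64", "int16", "uint8")) {
  datatype <- match.arg(datatype)
  code <- c(float32 = 16L, float64 = 64L, int16 = 4L, uint8 = 2L)[[datatype]]
  dt <- nifti_dtypes[[as.character(code)]]
  data <- as.array(data)
  nd <- length(dim(data))
  if (nd < 3L || nd > 4L) stop("data must be a 3D or 4D array", call. = FALSE)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  dims <- integer(8L)
  dims[1L] <- nd
  dims[2:(1 + nd)] <- dim(data)
  dims[dims == 0L] <- 1L
  pixdim <- numeric(8L)
  pixdim[1] <- 1
  pixdim[2:4] <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (nd == 4L) pixdim[5] <- 1

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  pad <- function(s, n) {
    r <- charToRaw(s)
    c(r[seq_len(min(length(r), n))], raw(max(0L, n - length(r))))
  }
  wb(348L, 4L)                                   # sizeof_hdr
  writeBin(raw(36L), con)                        # data_type..dim_info
  wb(dims, 2L)                                   # dim
  wb(numeric(3L), 4L)                            # intent_p1..p3
  wb(0L, 2L)                                     # intent_code
  wb(code, 2L)                                   # datatype
  wb(dt$bitpix, 2L)                              # bitpix
  wb(0L, 2L)                                     # slice_start
  wb(pixdim, 4L)                                 # pixdim
  wb(352, 4L)                                    # vox_offset
  wb(1, 4L)                                      # scl_slope
  wb(0, 4L)                                      # scl_inter
  writeBin(raw(28L), con)                        # slice/cal/gl fields
  writeBin(pad("congradr", 80L), con)            # descrip
  writeBin(raw(24L), con)                        # aux_file
  wb(0L, 2L)                                     # qform_code
  wb(2L, 2L)                                     # sform_code
  wb(numeric(6L), 4L)                            # quaternions/offsets
  wb(as.numeric(t(affine[1:3, ])), 4L)           # srow_x/y/z
  writeBin(raw(16L), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  writeBin(raw(4L), con)                         # extension indicator
  vals <- as.numeric(data)
  if (dt$what == "integer") {
    wb(as.integer(round(vals)), dt$size)
  } else {
    wb(vals, dt$size)
  }
  invisible(path)
}
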