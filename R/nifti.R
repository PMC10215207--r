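# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only the fields this pipeline needs are interpreted: dim, datatype,
# pixdim, vox_offset and the scl_slope/scl_inter rescale.  Voxel order on
# disk is preserved exactly: voxel (i,j,k) on disk is voxel (i,j,k) in the
# returned array; no reorientation to RAS/LPS is attempted and the stored
# spacing is carried through untouched.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`).  The voxel
#' array is returned in on-disk order (no axis reordering); the per-axis
#' voxel spacing in millimetres is taken from `pixdim`.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (numeric array), `spacing`
#'   (numeric vector of voxel sizes in mm, one per axis) and `dims`
#'   (integer vector of voxel counts).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- open_maybe_gz(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header in ", path)

  parse_hdr <- function(raw, endian) {
    rc <- rawConnection(raw)
    on.exit(close(rc))
    sizeof_hdr <- readBin(rc, "integer", 1L, size = 4L, endian = endian)
    seek(rc, 40L)
    dim <- readBin(rc, "integer", 8L, size = 2L, endian = endian)
    seek(rc, 70L)
    datatype <- readBin(rc, "integer", 1L, size = 2L, endian = endian)
    bitpix <- readBin(rc, "integer", 1L, size = 2L, endian = endian)
    seek(rc, 76L)
    pixdim <- readBin(rc, "double", 8L, size = 4L, endian = endian)
    vox_offset <- readBin(rc, "double", 1L, size = 4L, endian = endian)
    scl_slope <- readBin(rc, "double", 1L, size = 4L, endian = endian)
    scl_inter <- readBin(rc, "double", 1L, size = 4L, endian = endian)
    seek(rc, 344L)
    magic <- rawToChar(readBin(rc, "raw", 3L))
    list(sizeof_hdr = sizeof_hdr, dim = dim, datatype = datatype,
         bitpix = bitpix, pixdim = pixdim, vox_offset = vox_offset,
         scl_slope = scl_slope, scl_inter = scl_inter, magic = magic)
  }

  endian <- "little"
  h <- parse_hdr(hdr_raw, endian)
  if (h$sizeof_hdr != 348L) {
    endian <- "big"
    h <- parse_hdr(hdr_raw, endian)
    if (h$sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
  }
  if (!h$magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic in ", path)

  ndim <- h$dim[1]
  if (ndim < 1L || ndim > 7L) stop("corrupt dim field in ", path)
  dims <- h$dim[2:(1 + ndim)]
  dims <- dims[dims > 0L]
  n <- prod(dims)
  dt <- NIFTI_DTYPES[[as.character(h$datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", h$datatype, " in ", path)

  skip <- round(h$vox_offset) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = n, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  vals <- as.double(vals)
  if (!is.na(h$scl_slope) && h$scl_slope != 0 &&
      !(h$scl_slope == 1 && h$scl_inter == 0)) {
    vals <- vals * h$scl_slope + h$scl_inter
  }
  data <- array(vals, dim = dims)
  spacing <- h$pixdim[2:(1 + length(dims))]
  spacing[!is.finite(spacing) | spacing <= 0] <- 1
  list(data = data, spacing = spacing, dims = dims)
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3D array as a single-file NIfTI-1 image.  Integer-valued
#' arrays (e.g. label volumes) are stored losslessly as 16-bit integers;
#' everything else is stored as 64-bit float so that write/read
#' round-trips are value-exact.
#'
#' @param data 3D numeric array of finite values.
#' @param path Output path; a `.gz` suffix selects gzip compression.
#' @param spacing Voxel size in mm per axis (length 3).
#' @param create_dirs Create missing parent directories (default `FALSE`;
#'   without it a missing parent is an error).
#' @return Invisibly, `path`.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1), create_dirs = FALSE) {
  if (length(dim(data)) != 3L) stop("write_nifti expects a 3D array")
  if (!all(is.finite(data))) stop("write_nifti: data contains non-finite values")
  parent <- dirname(path)
  if (!dir.exists(parent)) {
    if (create_dirs) dir.create(parent, recursive = TRUE)
    else stop("parent directory does not exist: ", parent)
  }
  dims <- dim(data)
  integral <- all(data == round(data)) && max(abs(data)) <= 32767
  datatype <- if (integral) 4L else 64L
  bitpix <- if (integral) 16L else 64L

  con <- open_maybe_gz(path, "wb")
  on.exit(close(con), add = TRUE)
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                      #   0 sizeof_hdr
  w_raw(36L)                       #   4 data_type/db_name/extents/...
  w_i16(c(3L, dims, 1L, 1L, 1L, 1L))  # 40 dim[8]
  w_f32(c(0, 0, 0))                #  56 intent_p1..p3
  w_i16(0L)                        #  68 intent_code
  w_i16(datatype)                  #  70 datatype
  w_i16(bitpix)                    #  72 bitpix
  w_i16(0L)                        #  74 slice_start
  w_f32(c(1, spacing, 1, 1, 1, 1)) #  76 pixdim[8]
  w_f32(352)                       # 108 vox_offset
  w_f32(1)                         # 112 scl_slope
  w_f32(0)                         # 116 scl_inter
  w_i16(0L); writeBin(raw(1L), con); writeBin(raw(1L), con)  # 120 slice_end/code/xyzt_units
  w_f32(c(0, 0, 0))                # 124 cal_max/cal_min/slice_duration
  w_f32(0)                         # 136 toffset
  w_i32(c(0L, 0L))                 # 140 glmax/glmin
  w_raw(80L)                       # 148 descrip
  w_raw(24L)                       # 228 aux_file
  w_i16(0L)                        # 252 qform_code
  w_i16(1L)                        # 254 sform_code
  w_f32(c(0, 0, 0))                # 256 quatern b,c,d
  w_f32(c(0, 0, 0))                # 268 qoffset x,y,z
  w_f32(c(spacing[1], 0, 0, 0))    # 280 srow_x
  w_f32(c(0, spacing[2], 0, 0))    # 296 srow_y
  w_f32(c(0, 0, spacing[3], 0))    # 312 srow_z
  w_raw(16L)                       # 328 intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # 344 magic
  w_raw(4L)                        # 348 extension indicator
  if (integral) {
    writeBin(as.integer(data), con, size = 2L, endian = "little")
  } else {
    writeBin(as.double(data), con, size = 8L, endian = "little")
  }
  invisible(path)
}
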