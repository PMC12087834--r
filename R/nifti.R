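## Minimal NIfTI-1 I/O.
##
## No NIfTI reader is available in this R stack, so the package carries a
## deliberately small implementation of the single-file ".nii" layout
## (348-byte header, magic "n+1", data at vox_offset). Gzipped files are
## handled transparently via gzfile(). Only the fields this package needs are
## interpreted: dim, pixdim, datatype, scl slope/intercept, vox_offset.
## qform/sform rotation decoding is out of scope; anatomical axis labels and
## laterality are carried by a JSON sidecar (see load_mask / write_mask).

.nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8, signed = TRUE)    # float64
)

.nifti_open <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) and returns the
#' data array together with the voxel spacing from the header. Supports the
#' integer and float datatypes produced by common neuroimaging tools; only
#' 3D volumes are accepted by downstream mask analysis.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (numeric array), `spacing` (numeric
#'   vector, mm per voxel along each array dimension) and `dim`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- .nifti_open(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348)
  if (length(hdr_raw) < 348) stop("not a NIfTI-1 file (header truncated): ", path)
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4, endian = "little")
  endian <- "little"
  if (sizeof_hdr != 348L) {
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4, endian = "big")
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
    endian <- "big"
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)
  rd <- function(off, what, n, size) {
    readBin(hdr_raw[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian)
  }
  dims <- rd(40, "integer", 8, 2)
  ndim <- dims[1]
  if (ndim < 1 || ndim > 7) stop("corrupt NIfTI header: dim[0] = ", ndim)
  shape <- dims[2:(1 + ndim)]
  datatype <- rd(70, "integer", 1, 2)
  dt <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  pixdim <- rd(76, "double", 8, 4)
  spacing <- pixdim[2:(1 + ndim)]
  vox_offset <- rd(108, "double", 1, 4)
  scl_slope <- rd(112, "double", 1, 4)
  scl_inter <- rd(116, "double", 1, 4)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n_vox <- prod(shape)
  data <- readBin(con, dt$what, n = n_vox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(data) != n_vox) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  # pixdim is float32 in the header; snap to 7 significant digits so values
  # like 1.05 mm survive the round trip exactly
  list(data = array(as.numeric(data), dim = shape),
       spacing = signif(as.numeric(spacing), 7), dim = shape)
}

#' Write a NIfTI-1 volume
#'
#' Writes a numeric array as a single-file NIfTI-1 image with voxel spacing
#' in the header. Binary masks are stored as uint8, anything else as float64.
#'
#' @param data Numeric or logical array (up to 7 dimensions).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param spacing Numeric vector of per-dimension voxel sizes in mm.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing = rep(1, length(dim(data)))) {
  shape <- dim(data)
  if (is.null(shape)) stop("'data' must be an array")
  if (length(spacing) != length(shape)) {
    stop("'spacing' must have one entry per array dimension")
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("voxel spacing must be positive and finite")
  }
  vals <- as.numeric(data)
  is_mask <- all(vals %in% c(0, 1))
  datatype <- if (is_mask) 2L else 64L
  bitpix <- if (is_mask) 8L else 64L

  hdr <- raw(348)
  put <- function(off, x, size, what = "integer") {
    b <- writeBin(x, raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <<- b
    invisible(NULL)
  }
  put(0, 348L, 4)
  dims <- integer(8)
  dims[1] <- length(shape)
  dims[2:(1 + length(shape))] <- as.integer(shape)
  if (length(shape) < 7) dims[(2 + length(shape)):8] <- 1L
  put(40, dims, 2)
  put(70, datatype, 2)
  put(72, bitpix, 2)
  pixdim <- numeric(8)
  pixdim[2:(1 + length(spacing))] <- spacing
  if (length(spacing) < 7) pixdim[(2 + length(spacing)):8] <- 1
  put(76, pixdim, 4, "double")
  put(108, 352, 4, "double")       # vox_offset
  put(112, 1, 4, "double")         # scl_slope
  put(123, 10L, 1)                 # xyzt_units: NIFTI_UNITS_MM | SEC
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0))

  con <- .nifti_open(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)            # extension indicator
  if (is_mask) {
    writeBin(as.integer(vals), con, size = 1)
  } else {
    writeBin(vals, con, size = 8)
  }
  invisible(path)
}
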