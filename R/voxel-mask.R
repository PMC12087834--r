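#' Voxel mask container
#'
#' A `voxel_mask` bundles a 3D binary grid with its voxel spacing (mm), the
#' mapping of grid axes to anatomical axes, and eye laterality. Grid axis
#' labels use the anatomical shorthand `"AP"` (anterior-posterior), `"NT"`
#' (nasal-temporal) and `"IS"` (inferior-superior); the three labels must be
#' a permutation of these.
#'
#' @param grid 3D array; any value `> 0` is treated as foreground.
#' @param spacing Numeric length-3 vector of voxel sizes in mm along the grid
#'   axes. Default mirrors the acquisition geometry (1.05 x 1 x 1 mm).
#' @param axis_labels Character length-3: anatomical label of each grid axis.
#' @param laterality `"left"` or `"right"`.
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(grid, spacing = c(1.05, 1, 1),
                       axis_labels = c("AP", "NT", "IS"),
                       laterality = "right") {
  if (length(dim(grid)) != 3) {
    stop("mask grid must be 3D, got ", length(dim(grid)), " dimensions")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 positive finite values (mm)")
  }
  if (!setequal(axis_labels, c("AP", "NT", "IS")) || length(axis_labels) != 3) {
    stop("axis_labels must be a permutation of AP, NT, IS")
  }
  laterality <- match.arg(laterality, c("left", "right"))
  structure(
    list(grid = array(grid > 0, dim = dim(grid)),
         spacing = spacing,
         axis_labels = as.character(axis_labels),
         laterality = laterality),
    class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat("<voxel_mask> ", paste(dim(x$grid), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, ", sum(x$grid), " foreground, ", x$laterality, " eye\n", sep = "")
  invisible(x)
}

n_foreground <- function(mask) sum(mask$grid)

assert_nonempty <- function(mask) {
  if (n_foreground(mask) == 0) {
    stop("mask has no foreground voxels; analysis is undefined")
  }
  invisible(mask)
}

# mm coordinates (voxel centers) of all foreground voxels, one row per voxel.
# Index i maps to coordinate (i - 1) * spacing; anisotropic spacing is applied
# here, never by resampling.
foreground_coords_mm <- function(mask) {
  idx <- which(mask$grid, arr.ind = TRUE)
  sweep(idx - 1, 2, mask$spacing, `*`)
}

#' Write a voxel mask to NIfTI plus JSON sidecar
#'
#' The grid and spacing go into a NIfTI-1 file; laterality and the grid-axis
#' to anatomical-axis mapping go into `<path without .nii[.gz]>.json`.
#'
#' @param mask A [voxel_mask].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  write_nifti(mask$grid * 1L, path, spacing = mask$spacing)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(laterality = mask$laterality, axis_labels = mask$axis_labels),
    sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a voxel mask from NIfTI plus JSON sidecar
#'
#' Values `> 0` become foreground. Spacing must be present in the header;
#' laterality and axis labels must be present in the sidecar. A 4D (or other
#' non-3D) grid is rejected.
#'
#' @param path `.nii` or `.nii.gz` file written by [write_mask()] or any
#'   NIfTI-1 producer.
#' @param sidecar Path to the JSON sidecar; defaults to `path` with the
#'   extension swapped for `.json`.
#' @return A [voxel_mask].
#' @export
load_mask <- function(path, sidecar = NULL) {
  img <- read_nifti(path)
  if (length(img$dim) != 3) {
    stop("expected a 3D mask, got a ", length(img$dim), "D grid in ", path)
  }
  missing_meta <- character()
  if (any(!is.finite(img$spacing)) || any(img$spacing <= 0)) {
    missing_meta <- c(missing_meta, "voxel spacing (pixdim)")
  }
  sidecar <- sidecar %||% sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  if (is.null(meta$laterality)) missing_meta <- c(missing_meta, "laterality (sidecar)")
  if (is.null(meta$axis_labels)) missing_meta <- c(missing_meta, "axis_labels (sidecar)")
  if (length(missing_meta)) {
    stop("cannot resolve mask metadata for ", path, "; missing: ",
         paste(missing_meta, collapse = ", "))
  }
  voxel_mask(img$data > 0, spacing = img$spacing,
             axis_labels = unlist(meta$axis_labels),
             laterality = meta$laterality)
}
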