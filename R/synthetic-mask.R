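#' Specification of a synthetic voxelised ellipsoid
#'
#' Describes the ground-truth posterior-eye ellipsoid that
#' [make_ellipsoid_mask()] voxelises: semidiameters along the
#' anterior-posterior (`a`), nasal-temporal (`b`) and inferior-superior (`c`)
#' anatomical axes, an optional rigid rotation and centre offset, voxel
#' spacing, boundary noise, and an optional anterior truncation emulating the
#' lens-excluded chamber.
#'
#' @param a,b,c Semidiameters in mm (anterior-posterior, nasal-temporal,
#'   inferior-superior). Must be positive.
#' @param rotation Euler angles in degrees (rotation about the AP, NT and IS
#'   grid axes, applied in that order).
#' @param center Centre offset in mm relative to the grid centre.
#' @param spacing Voxel size in mm per grid axis; default 1.05 x 1 x 1 mm
#'   (acquisition geometry), isotropic 1 mm is typical for tests.
#' @param surface_noise_sd SD (mm) of zero-mean radial noise applied to the
#'   boundary decision. 0 gives an exact voxelisation.
#' @param anterior_truncation_fraction Fraction of the anterior-posterior
#'   diameter removed from the anterior end, in `[0, 0.3]` (must stay below
#'   0.5 so the posterior segment remains the dominant body).
#' @param laterality `"left"` or `"right"` (metadata only).
#' @param seed Integer seed used for the surface noise; required when
#'   `surface_noise_sd > 0`. All randomness flows from this seed.
#' @return An object of class `ellipsoid_spec`.
#' @export
ellipsoid_spec <- function(a, b, c, rotation = c(0, 0, 0), center = c(0, 0, 0),
                           spacing = c(1.05, 1, 1), surface_noise_sd = 0,
                           anterior_truncation_fraction = 0,
                           laterality = "right", seed = NULL) {
  semis <- c(a = a, b = b, c = c)
  if (any(!is.finite(semis)) || any(semis <= 0)) {
    stop("semidiameters a, b, c must be positive (got ",
         paste(signif(semis, 4), collapse = ", "), ")")
  }
  if (any(spacing <= 0)) stop("spacing components must be positive")
  if (surface_noise_sd < 0) stop("surface_noise_sd must be >= 0")
  if (anterior_truncation_fraction < 0 || anterior_truncation_fraction >= 0.5) {
    stop("anterior_truncation_fraction must be in [0, 0.5)")
  }
  if (anterior_truncation_fraction > 0.3) {
    stop("anterior_truncation_fraction above 0.3 is outside the supported range")
  }
  if (surface_noise_sd > 0 && is.null(seed)) {
    stop("a seed is required when surface_noise_sd > 0")
  }
  structure(
    list(a = a, b = b, c = c,
         rotation = as.numeric(rotation), center = as.numeric(center),
         spacing = as.numeric(spacing),
         surface_noise_sd = surface_noise_sd,
         anterior_truncation_fraction = anterior_truncation_fraction,
         laterality = match.arg(laterality, c("left", "right")),
         seed = seed),
    class = "ellipsoid_spec")
}

#' Voxelise a rotated ellipsoid into a binary mask
#'
#' A voxel is foreground iff its centre lies inside the rotated, optionally
#' anteriorly truncated ellipsoid; with `surface_noise_sd > 0` the radial
#' boundary decision is perturbed by zero-mean Gaussian noise of that SD
#' (in mm). Voxel membership is decided at voxel centres, which keeps the
#' counted volume comparable to the analytic \eqn{4/3 \pi abc}.
#'
#' @param spec An [ellipsoid_spec()].
#' @param dims Optional integer grid dimensions. When omitted the grid is
#'   sized to contain the rotated ellipsoid plus a noise margin; when given,
#'   an ellipsoid exceeding the grid is an error, never a silent clip.
#' @return A [voxel_mask] with the generating spec attached as attribute
#'   `"ground_truth"`.
#' @export
make_ellipsoid_mask <- function(spec, dims = NULL) {
  stopifnot(inherits(spec, "ellipsoid_spec"))
  R <- rotation_matrix(spec$rotation)
  semis <- c(spec$a, spec$b, spec$c)
  # support function of the rotated ellipsoid along each grid axis
  extent <- sqrt(colSums((semis * t(R))^2))
  margin <- 4 * spec$surface_noise_sd + 2 * spec$spacing
  half_needed <- extent + abs(spec$center) + margin
  if (is.null(dims)) {
    dims <- 2L * as.integer(ceiling(half_needed / spec$spacing)) + 1L
  } else {
    dims <- as.integer(dims)
    have <- (dims - 1) / 2 * spec$spacing
    if (any(have < extent + abs(spec$center))) {
      stop("ellipsoid exceeds the requested grid bounds along axis ",
           paste(which(have < extent + abs(spec$center)), collapse = ", "),
           "; enlarge dims instead of clipping")
    }
  }
  centre_mm <- (dims - 1) / 2 * spec$spacing + spec$center

  ax <- (seq_len(dims[1]) - 1) * spec$spacing[1] - centre_mm[1]
  ay <- (seq_len(dims[2]) - 1) * spec$spacing[2] - centre_mm[2]
  az <- (seq_len(dims[3]) - 1) * spec$spacing[3] - centre_mm[3]
  # voxel-centre coordinates relative to ellipsoid centre, one row per voxel
  P <- cbind(rep(ax, times = dims[2] * dims[3]),
             rep(rep(ay, each = dims[1]), times = dims[3]),
             rep(az, each = dims[1] * dims[2]))
  Q <- P %*% R                      # rows: t(R) %*% p = ellipsoid-frame coords
  m <- sqrt((Q[, 1] / spec$a)^2 + (Q[, 2] / spec$b)^2 + (Q[, 3] / spec$c)^2)

  if (spec$surface_noise_sd > 0) {
    r <- sqrt(rowSums(P^2))
    # inside iff r <= r_surface + eps, with r_surface = r / m along the ray
    eps <- with_local_seed(spec$seed,
                           rnorm(nrow(P), mean = 0, sd = spec$surface_noise_sd))
    inside <- (r - r / pmax(m, .Machine$double.eps)) <= eps
    inside[m == 0] <- TRUE
  } else {
    inside <- m <= 1
  }

  f <- spec$anterior_truncation_fraction
  if (f > 0) {
    # cut plane perpendicular to the AP axis, removing the anterior cap
    inside <- inside & (Q[, 1] <= spec$a * (1 - 2 * f))
  }

  grid <- array(inside, dim = dims)
  mask <- voxel_mask(grid, spacing = spec$spacing,
                     laterality = spec$laterality)
  attr(mask, "ground_truth") <- spec
  attr(mask, "center_mm") <- centre_mm
  mask
}

# run expr under a given seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
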