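#' Fundus scene container
#'
#' A `fundus_scene` holds the geometric annotations from which the
#' twelve-feature morphometry battery is computed: the optic disc (OD)
#' ellipse, the fovea location, vessel centreline polylines with per-point
#' widths and arteriole/venule labels, an optional intensity raster, eye
#' laterality and the magnification inputs (spherical equivalent refraction
#' and corneal radius).
#'
#' Scene coordinates are in pixels with y increasing upward. For right eyes
#' the fovea lies in the +x direction from the disc; left-eye scenes are the
#' mirror image (fovea towards -x) and are harmonised internally by
#' mirroring about the vertical axis, so features are laterality-invariant.
#'
#' @param od_ellipse List with `center` (x, y), `semi_major`, `semi_minor`
#'   (pixels, `semi_major >= semi_minor > 0`) and `angle` (major-axis angle
#'   in degrees from horizontal).
#' @param fovea Numeric (x, y) in pixels.
#' @param vessels List of vessels; each a list with `points` (n x 2 matrix,
#'   n >= 2), `widths` (length n, positive), `type` (`"arteriole"` or
#'   `"venule"`) and `arcade` (`"superior-temporal"`, `"inferior-temporal"`
#'   or `"other"`).
#' @param intensity Optional list with `grid` (matrix, rows indexed by y,
#'   columns by x) and `origin` (scene coordinate of grid cell `[1, 1]`).
#' @param laterality `"left"` or `"right"`.
#' @param ser Spherical equivalent refraction in dioptres.
#' @param corneal_radius Corneal radius in mm (optional, default 7.8).
#' @return An object of class `fundus_scene`.
#' @export
fundus_scene <- function(od_ellipse, fovea, vessels = list(), intensity = NULL,
                         laterality = "right", ser = 0, corneal_radius = 7.8) {
  laterality <- match.arg(laterality, c("left", "right"))
  stopifnot(is.list(od_ellipse),
            all(c("center", "semi_major", "semi_minor", "angle") %in%
                  names(od_ellipse)))
  if (!(od_ellipse$semi_major >= od_ellipse$semi_minor) ||
      od_ellipse$semi_minor <= 0) {
    stop("OD ellipse requires semi_major >= semi_minor > 0")
  }
  for (v in vessels) {
    if (!is.matrix(v$points) || nrow(v$points) < 2) {
      stop("vessel polylines need at least 2 points")
    }
    if (length(v$widths) != nrow(v$points) || any(v$widths <= 0)) {
      stop("vessel widths must be positive, one per polyline point")
    }
    if (!v$type %in% c("arteriole", "venule")) {
      stop("vessel type must be 'arteriole' or 'venule'")
    }
  }
  structure(
    list(od_ellipse = od_ellipse, fovea = as.numeric(fovea),
         vessels = vessels, intensity = intensity, laterality = laterality,
         ser = ser, corneal_radius = corneal_radius),
    class = "fundus_scene")
}

#' Default constants of the magnification model
#'
#' The correction follows the camera-and-eye telecentric model in which the
#' true retinal dimension is proportional to `q = 0.01306 (AL - 1.82)` with
#' AL the axial length in mm. AL is estimated from corneal radius (CR, mm)
#' and spherical equivalent refraction (SER, D) by a linear regression
#' `AL = al0 + al_cr * CR + al_ser * SER`. The regression constants here are
#' package defaults chosen to reproduce typical adult biometry (AL around
#' 23.4 mm at CR 7.8 mm, about 0.3 mm axial elongation per dioptre of
#' myopia); they are exposed so a calibrated set can be substituted.
#'
#' @param al0,al_cr,al_ser Axial-length regression constants.
#' @param cr_ref Reference corneal radius (mm) at which an emmetropic eye has
#'   magnification factor exactly 1.
#' @return Named list of constants.
#' @export
mag_constants <- function(al0 = 0.58, al_cr = 2.92, al_ser = -0.299,
                          cr_ref = 7.8) {
  list(al0 = al0, al_cr = al_cr, al_ser = al_ser, cr_ref = cr_ref)
}

#' Ocular magnification factor for dimensional fundus metrics
#'
#' Multiplicative factor applied to linear dimensional metrics (distances,
#' calibres; areas get the square). Anchored to 1 at the emmetropic
#' reference (SER = 0 at the reference corneal radius) and monotone in SER:
#' a more myopic (longer) eye has larger true retinal dimensions per image
#' pixel, hence a factor above 1.
#'
#' @param ser Spherical equivalent refraction in dioptres, in `[-20, 10]`.
#' @param corneal_radius Corneal radius in mm, in `[6.5, 9.5]`.
#' @param constants Constants from [mag_constants()].
#' @return Unitless scale factor.
#' @export
magnification_factor <- function(ser, corneal_radius = 7.8,
                                 constants = mag_constants()) {
  if (any(!is.finite(ser)) || any(ser < -20) || any(ser > 10)) {
    stop("SER out of plausible range [-20, 10] D")
  }
  if (any(!is.finite(corneal_radius)) || any(corneal_radius < 6.5) ||
      any(corneal_radius > 9.5)) {
    stop("corneal radius out of plausible range [6.5, 9.5] mm")
  }
  al <- constants$al0 + constants$al_cr * corneal_radius + constants$al_ser * ser
  al_ref <- constants$al0 + constants$al_cr * constants$cr_ref
  (al - 1.82) / (al_ref - 1.82)
}

scene_mag_factor <- function(scene) {
  magnification_factor(scene$ser, scene$corneal_radius %||% 7.8)
}

# mirror-harmonised OD->fovea offset (x temporal-positive, y up)
od_fovea_offset <- function(scene) {
  d <- scene$fovea - scene$od_ellipse$center
  if (all(d == 0)) {
    stop("fovea coincides with the OD centre; angle and distance undefined")
  }
  if (scene$laterality == "left") d[1] <- -d[1]
  d
}

#' Optic disc to fovea distance
#'
#' Euclidean distance between OD centre and fovea, magnification-corrected.
#'
#' @param scene A [fundus_scene].
#' @return Distance in pixels (corrected scale).
#' @export
od_fovea_distance <- function(scene) {
  d <- od_fovea_offset(scene)
  sqrt(sum(d^2)) * scene_mag_factor(scene)
}

#' Optic disc to fovea angle
#'
#' Signed angle (degrees) of the OD-to-fovea ray against the horizontal
#' through the OD centre; negative when the fovea lies below that
#' horizontal. Left-eye scenes are mirrored about the vertical axis first so
#' the temporal direction is consistent across lateralities: more negative
#' always means greater angular separation.
#'
#' @param scene A [fundus_scene].
#' @return Angle in degrees.
#' @export
od_fovea_angle <- function(scene) {
  d <- od_fovea_offset(scene)
  atan2(d[2], d[1]) * 180 / pi
}

#' Optic disc area, orientation and ovality
#'
#' Area uses the standard ellipse formula (pi times the semi-axes), scaled
#' by the squared magnification factor. Orientation is the angle between the
#' image horizontal and the disc major axis, folded to `[0, 90]` degrees (an
#' axis, not a ray): larger values mean a more vertical, less oblique disc.
#' A circular disc has no oblique axis and reports 90 by convention.
#' Ovality is major/minor axis length, always `>= 1`.
#'
#' @param scene A [fundus_scene].
#' @return Named vector `c(od_area, od_orientation, od_ovality)`.
#' @export
od_metrics <- function(scene) {
  e <- scene$od_ellipse
  f <- scene_mag_factor(scene)
  area <- pi * e$semi_major * e$semi_minor * f^2
  ovality <- e$semi_major / e$semi_minor
  if (e$semi_major == e$semi_minor) {
    orient <- 90
  } else {
    phi <- e$angle %% 180
    orient <- min(phi, 180 - phi)
  }
  c(od_area = area, od_orientation = orient, od_ovality = ovality)
}

# one summary width per vessel: median of the per-point widths
vessel_summary_widths <- function(scene, type) {
  w <- vapply(scene$vessels, function(v) {
    if (v$type == type) median(v$widths) else NA_real_
  }, numeric(1))
  w[!is.na(w)]
}

#' Iterative big-six vessel-calibre reduction
#'
#' The revised summarisation of the six widest vessels of a type: repeatedly
#' sort, pair the largest with the smallest, combine each pair as
#' `w_hat = k * sqrt(w1^2 + w2^2)`, carry the median unpaired when the count
#' is odd, and iterate to one value.
#'
#' @param widths Numeric vessel summary widths.
#' @param k Branching constant: 0.88 (arterioles) or 0.95 (venules).
#' @return Single combined calibre.
#' @export
knudtson_reduce <- function(widths, k) {
  w <- as.numeric(widths)
  if (!length(w)) stop("no widths to reduce")
  while (length(w) > 1) {
    w <- sort(w, decreasing = TRUE)
    n <- length(w)
    carry <- numeric(0)
    if (n %% 2 == 1) {
      mid <- (n + 1) / 2
      carry <- w[mid]
      w <- w[-mid]
      n <- n - 1
    }
    half <- n / 2
    paired <- k * sqrt(w[seq_len(half)]^2 + w[n:(half + 1)]^2)
    w <- c(paired, carry)
  }
  w
}

crx_equivalent <- function(scene, type, k) {
  w <- vessel_summary_widths(scene, type)
  if (!length(w)) return(feature_sentinel())
  w <- sort(w, decreasing = TRUE)
  w <- w[seq_len(min(6, length(w)))]
  knudtson_reduce(w, k) * scene_mag_factor(scene)
}

#' Central retinal arteriolar equivalent (CRAE)
#'
#' Big-six iterative pairing over the widest arterioles with branching
#' constant 0.88, magnification-corrected. Returns `NA` when the scene has
#' no arterioles (missing-value sentinel, not an error).
#'
#' @param scene A [fundus_scene].
#' @param k Arteriolar branching constant (default 0.88).
#' @return Calibre in pixels, or `NA`.
#' @export
crae <- function(scene, k = 0.88) crx_equivalent(scene, "arteriole", k)

#' Central retinal venular equivalent (CRVE)
#'
#' As [crae()] but over venules with branching constant 0.95.
#'
#' @param scene A [fundus_scene].
#' @param k Venular branching constant (default 0.95).
#' @return Calibre in pixels, or `NA`.
#' @export
crve <- function(scene, k = 0.95) crx_equivalent(scene, "venule", k)

polyline_arc_chord <- function(points) {
  segs <- diff(points)
  arc <- sum(sqrt(rowSums(segs^2)))
  chord <- sqrt(sum((points[nrow(points), ] - points[1, ])^2))
  c(arc = arc, chord = chord)
}

#' Pooled retinal vessel tortuosity
#'
#' Per-vessel tortuosity is arc length / chord length - 1; the scene value
#' is the arc-length-weighted mean over all vessels (arterioles and venules
#' pooled). Closed loops (zero chord) are excluded with a warning.
#'
#' @param scene A [fundus_scene].
#' @return Unitless tortuosity (0 for perfectly straight vessels).
#' @export
vessel_tortuosity <- function(scene) {
  if (!length(scene$vessels)) return(feature_sentinel())
  tor <- len <- numeric(0)
  for (v in scene$vessels) {
    ac <- polyline_arc_chord(v$points)
    if (ac["chord"] <= 0) {
      warning("vessel with zero chord (closed loop) excluded from tortuosity")
      next
    }
    tor <- c(tor, ac["arc"] / ac["chord"] - 1)
    len <- c(len, ac["arc"])
  }
  if (!length(tor)) return(feature_sentinel())
  sum(tor * len) / sum(len)
}

#' Box-counting fractal dimension of a binary vessel map
#'
#' Slope of log(occupied box count) versus log(1/box size) over a dyadic
#' ladder of box sizes from side/4 down to 2 pixels, fitted by least
#' squares. 1 is line-like, 2 plane-filling.
#'
#' @param map Logical/numeric matrix (side at least 64 px).
#' @param min_fg Minimum foreground pixels below which `NA` is returned.
#' @return Fractal dimension, or `NA` for (near-)empty maps.
#' @export
vessel_fd <- function(map, min_fg = 10) {
  map <- map > 0
  if (min(dim(map)) < 64) stop("vessel map side must be at least 64 px")
  fg <- which(map, arr.ind = TRUE)
  if (nrow(fg) < min_fg) return(feature_sentinel())
  side <- min(dim(map))
  sizes <- 2^(seq.int(floor(log2(side / 4)), 1))
  if (length(sizes) < 5) stop("grid too small for a 5-point box ladder")
  counts <- vapply(sizes, function(s) {
    nrow(unique(cbind((fg[, 1] - 1) %/% s, (fg[, 2] - 1) %/% s)))
  }, numeric(1))
  fit <- lm(log(counts) ~ log(1 / sizes))
  unname(coef(fit)[2])
}

# rasterise vessel centrelines onto a square binary map for box counting
rasterize_vessels <- function(scene, side = 512) {
  pts <- do.call(rbind, lapply(scene$vessels, `[[`, "points"))
  if (is.null(pts) || nrow(pts) < 2) {
    return(matrix(FALSE, side, side))
  }
  rng <- apply(pts, 2, range)
  span <- max(rng[2, ] - rng[1, ], 1)
  map <- matrix(FALSE, side, side)
  for (v in scene$vessels) {
    p <- v$points
    for (i in seq_len(nrow(p) - 1)) {
      seg <- p[i + 1, ] - p[i, ]
      n <- max(2L, ceiling(sqrt(sum(seg^2)) / span * side * 2))
      tt <- seq(0, 1, length.out = n)
      xs <- p[i, 1] + tt * seg[1]
      ys <- p[i, 2] + tt * seg[2]
      cx <- pmin(side, pmax(1, floor((xs - rng[1, 1]) / span * (side - 1)) + 1))
      cy <- pmin(side, pmax(1, floor((ys - rng[1, 2]) / span * (side - 1)) + 1))
      map[cbind(cy, cx)] <- TRUE
    }
  }
  map
}

#' Temporal arcade concavity
#'
#' Points of the superior- and inferior-temporal arcades of the requested
#' vessel type are jointly expressed in a frame centred on the OD with the
#' first axis along the OD-to-fovea direction (the parabola's axis of
#' symmetry), then a parabola `u = b0 + b1 v + b2 v^2` is fitted by least
#' squares. The concavity is `b2`, positive when the arcade curves towards
#' the fovea (opens in the OD-to-fovea direction); the frame itself makes
#' the sign laterality-invariant.
#'
#' @param scene A [fundus_scene].
#' @param vessel_type `"arteriole"` or `"venule"`.
#' @return Quadratic coefficient (1/px), or `NA` with fewer than 5 arcade
#'   points.
#' @export
arcade_concavity <- function(scene, vessel_type = c("arteriole", "venule")) {
  vessel_type <- match.arg(vessel_type)
  sel <- Filter(function(v) {
    v$type == vessel_type &&
      v$arcade %in% c("superior-temporal", "inferior-temporal")
  }, scene$vessels)
  pts <- do.call(rbind, lapply(sel, `[[`, "points"))
  if (is.null(pts) || nrow(pts) < 5) return(feature_sentinel())
  od <- scene$od_ellipse$center
  e1 <- scene$fovea - od
  if (all(e1 == 0)) stop("fovea coincides with the OD centre")
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(-e1[2], e1[1])
  rel <- sweep(pts, 2, od)
  u <- as.numeric(rel %*% e1)
  v <- as.numeric(rel %*% e2)
  fit <- lm(u ~ v + I(v^2))
  unname(coef(fit)[3])
}

#' Foveal pixel intensity
#'
#' Mean intensity within a disc of the given radius centred on the fovea.
#' When the disc extends past the raster border the mean is taken over the
#' in-bounds intersection and the result carries attribute `clipped = TRUE`.
#'
#' @param scene A [fundus_scene] with an intensity raster.
#' @param radius Disc radius in pixels (default 10).
#' @return Mean intensity, or `NA` when the scene has no intensity grid.
#' @export
foveal_pixel_intensity <- function(scene, radius = 10) {
  if (is.null(scene$intensity)) return(feature_sentinel())
  g <- scene$intensity$grid
  origin <- scene$intensity$origin %||% c(0, 0)
  fx <- scene$fovea[1] - origin[1] + 1   # column
  fy <- scene$fovea[2] - origin[2] + 1   # row
  if (fx < 1 || fx > ncol(g) || fy < 1 || fy > nrow(g)) {
    stop("fovea lies outside the intensity grid")
  }
  cols <- seq_len(ncol(g)); rows <- seq_len(nrow(g))
  inside <- outer((rows - fy)^2, (cols - fx)^2, `+`) <= radius^2
  clipped <- fx - radius < 1 || fx + radius > ncol(g) ||
             fy - radius < 1 || fy + radius > nrow(g)
  out <- mean(g[inside])
  if (clipped) attr(out, "clipped") <- TRUE
  out
}

#' Names of the twelve fundus features
#' @return Character vector in canonical order.
#' @export
fundus_feature_names <- function() {
  c("od_fovea_distance", "od_fovea_angle", "od_area", "od_orientation",
    "od_ovality", "crae", "crve", "tortuosity", "fd",
    "arterial_concavity", "venous_concavity", "fpi")
}

#' Extract the full twelve-feature vector from a scene
#'
#' Magnification correction is applied to dimensional metrics only
#' (OD-fovea distance, OD area, CRAE, CRVE). Features that cannot be
#' computed (no vessels of a type, no intensity grid) are carried as `NA`
#' sentinels rather than errors.
#'
#' @param scene A [fundus_scene].
#' @param fd_side Side of the raster used for box counting (default 512).
#' @return One-row data.frame with the columns of [fundus_feature_names()].
#' @export
extract_features <- function(scene, fd_side = 512) {
  stopifnot(inherits(scene, "fundus_scene"))
  odm <- od_metrics(scene)
  fd_val <- if (length(scene$vessels)) {
    vessel_fd(rasterize_vessels(scene, side = fd_side))
  } else {
    feature_sentinel()
  }
  out <- data.frame(
    od_fovea_distance = od_fovea_distance(scene),
    od_fovea_angle = od_fovea_angle(scene),
    od_area = odm[["od_area"]],
    od_orientation = odm[["od_orientation"]],
    od_ovality = odm[["od_ovality"]],
    crae = crae(scene),
    crve = crve(scene),
    tortuosity = vessel_tortuosity(scene),
    fd = fd_val,
    arterial_concavity = arcade_concavity(scene, "arteriole"),
    venous_concavity = arcade_concavity(scene, "venule"),
    fpi = as.numeric(foveal_pixel_intensity(scene)),
    stringsAsFactors = FALSE)
  out
}
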