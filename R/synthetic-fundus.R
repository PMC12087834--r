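#' Generate a synthetic fundus scene with known ground truth
#'
#' Builds a geometric fundus annotation whose generating parameters are
#' recorded exactly: an OD ellipse, a fovea placed at a given distance and
#' angle from the disc (harmonised convention: temporal is +x, negative
#' angle means fovea below the disc horizontal), temporal arterial and
#' venous arcades following the parabola `u = coef * v^2` in the
#' OD-to-fovea frame, extra straight vessels to reach six arterioles and six
#' venules, optional sinusoidal waviness controlling tortuosity, and an
#' intensity raster with a darker foveal disc.
#'
#' Defaults mirror a typical 45-degree macula-centred photograph at roughly
#' 1000 px scene scale: OD-fovea distance around 300 px, OD-fovea angle
#' around -7 degrees, OD semi-axes 55 x 50 px, arcade coefficient 0.005/px,
#' arteriolar widths near 13 px and venular widths near 16 px.
#'
#' @param od_fovea_dist OD-to-fovea distance in px.
#' @param od_fovea_ang OD-to-fovea angle in degrees (negative = fovea below).
#' @param od_semi_major,od_semi_minor,od_angle OD ellipse geometry.
#' @param arcade_coef Parabola coefficient (1/px) of the temporal arcades.
#' @param arteriole_widths,venule_widths Per-vessel widths in px (six each by
#'   default; the first two of each type form the arcades).
#' @param waviness Amplitude (px) of the sinusoidal perturbation added to
#'   every vessel; 0 gives exactly straight/parabolic vessels.
#' @param wavelength Wavelength (px) of the perturbation.
#' @param laterality `"left"` scenes are stored mirrored about the vertical
#'   axis, as acquired.
#' @param ser,corneal_radius Magnification inputs.
#' @param fpi_value,background_value Intensity inside the foveal disc
#'   (radius 30 px) and elsewhere. `with_intensity = FALSE` omits the raster.
#' @param with_intensity Include the intensity raster?
#' @param seed Integer seed; all randomness (width jitter placement phases)
#'   derives from it.
#' @return A [fundus_scene] with attribute `"ground_truth"` recording every
#'   generating parameter plus the analytic feature values implied by them.
#' @export
make_fundus_scene <- function(od_fovea_dist = 300, od_fovea_ang = -7,
                              od_semi_major = 55, od_semi_minor = 50,
                              od_angle = 75, arcade_coef = 0.005,
                              arteriole_widths = c(14, 13.5, 13, 12.5, 12, 11.5),
                              venule_widths = c(17, 16.5, 16, 15.5, 15, 14.5),
                              waviness = 0, wavelength = 40,
                              laterality = "right", ser = 0,
                              corneal_radius = 7.8,
                              fpi_value = 60, background_value = 120,
                              with_intensity = TRUE, seed = 1) {
  laterality <- match.arg(laterality, c("left", "right"))
  if (od_fovea_dist <= 0) {
    stop("fovea coincident with the OD centre: od_fovea_dist must be > 0")
  }
  phases <- with_local_seed(seed, runif(24, 0, 2 * pi))

  od_center <- c(0, 0)
  ang <- od_fovea_ang * pi / 180
  fovea <- od_center + od_fovea_dist * c(cos(ang), sin(ang))
  e1 <- (fovea - od_center) / od_fovea_dist
  e2 <- c(-e1[2], e1[1])

  wavy <- function(tt, phase) {
    if (waviness == 0) rep(0, length(tt)) else
      waviness * sin(2 * pi * tt / wavelength + phase)
  }
  # arcade polyline in the OD->fovea frame: u = coef * v^2, normal-direction
  # waviness so the parabola fit stays unbiased at waviness = 0
  arcade_points <- function(sign_v, phase) {
    v <- sign_v * seq(15, 1.1 * od_fovea_dist * 0.8, by = 4)
    u <- arcade_coef * v^2
    w <- wavy(cumsum(c(0, abs(diff(v)))), phase)
    p <- cbind(u + w, v)
    t(apply(p, 1, function(q) od_center + q[1] * e1 + q[2] * e2))
  }
  straight_points <- function(theta, len, phase) {
    tt <- seq(0, len, by = 4)
    dir <- c(cos(theta), sin(theta))
    nrm <- c(-dir[2], dir[1])
    base <- outer(tt, dir)
    off <- outer(wavy(tt, phase), nrm)
    sweep(base + off, 2, od_center, `+`)
  }

  mk_vessel <- function(points, width, type, arcade) {
    list(points = points, widths = rep(width, nrow(points)),
         type = type, arcade = arcade)
  }
  vessels <- list(
    mk_vessel(arcade_points(+1, phases[1]), arteriole_widths[1], "arteriole",
              "superior-temporal"),
    mk_vessel(arcade_points(-1, phases[2]), arteriole_widths[2], "arteriole",
              "inferior-temporal"),
    mk_vessel(arcade_points(+1, phases[3]) + 8, venule_widths[1], "venule",
              "superior-temporal"),
    mk_vessel(arcade_points(-1, phases[4]) + 8, venule_widths[2], "venule",
              "inferior-temporal"))
  # remaining vessels: straight radial courses away from the macula
  angles <- seq(110, 250, length.out = 8) * pi / 180
  for (i in seq_along(angles)) {
    type <- if (i %% 2 == 1) "arteriole" else "venule"
    widths <- if (type == "arteriole") arteriole_widths else venule_widths
    idx <- 2 + ceiling(i / 2)
    vessels[[length(vessels) + 1]] <-
      mk_vessel(straight_points(angles[i], 220, phases[4 + i]),
                widths[idx], type, "other")
  }

  intensity <- NULL
  if (with_intensity) {
    half <- 450
    n <- 2 * half + 1
    origin <- c(-half + od_fovea_dist / 2, -half)
    cols <- origin[1] + seq_len(n) - 1
    rows <- origin[2] + seq_len(n) - 1
    dist2 <- outer((rows - fovea[2])^2, (cols - fovea[1])^2, `+`)
    grid <- matrix(background_value, n, n)
    grid[dist2 <= 30^2] <- fpi_value
    intensity <- list(grid = grid, origin = origin)
  }

  mirror <- function(p) { p[, 1] <- -p[, 1]; p }
  if (laterality == "left") {
    fovea[1] <- -fovea[1]
    vessels <- lapply(vessels, function(v) { v$points <- mirror(v$points); v })
    if (!is.null(intensity)) {
      intensity$grid <- intensity$grid[, ncol(intensity$grid):1]
      intensity$origin[1] <- -(intensity$origin[1] + ncol(intensity$grid) - 1)
    }
    od_angle_store <- 180 - od_angle
  } else {
    od_angle_store <- od_angle
  }

  scene <- fundus_scene(
    od_ellipse = list(center = od_center, semi_major = od_semi_major,
                      semi_minor = od_semi_minor, angle = od_angle_store),
    fovea = fovea, vessels = vessels, intensity = intensity,
    laterality = laterality, ser = ser, corneal_radius = corneal_radius)

  f <- magnification_factor(ser, corneal_radius)
  phi <- od_angle %% 180
  truth <- list(
    od_fovea_dist = od_fovea_dist, od_fovea_ang = od_fovea_ang,
    od_semi_major = od_semi_major, od_semi_minor = od_semi_minor,
    od_angle = od_angle, arcade_coef = arcade_coef,
    arteriole_widths = arteriole_widths, venule_widths = venule_widths,
    waviness = waviness, seed = seed, laterality = laterality,
    features = list(
      od_fovea_distance = od_fovea_dist * f,
      od_fovea_angle = od_fovea_ang,
      od_area = pi * od_semi_major * od_semi_minor * f^2,
      od_orientation = if (od_semi_major == od_semi_minor) 90 else
        min(phi, 180 - phi),
      od_ovality = od_semi_major / od_semi_minor,
      crae = knudtson_reduce(sort(arteriole_widths, decreasing = TRUE)[1:6],
                             0.88) * f,
      crve = knudtson_reduce(sort(venule_widths, decreasing = TRUE)[1:6],
                             0.95) * f,
      arterial_concavity = arcade_coef,
      venous_concavity = arcade_coef,
      fpi = if (with_intensity) fpi_value else NA_real_))
  attr(scene, "ground_truth") <- truth
  scene
}
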