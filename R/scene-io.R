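#' Write a fundus scene to JSON
#'
#' Serialises the geometric annotation (OD ellipse, fovea, vessel polylines
#' with widths, laterality, magnification inputs). The intensity raster is
#' included only when `with_intensity = TRUE`; for large rasters prefer
#' regenerating them.
#'
#' @param scene A [fundus_scene].
#' @param path Output `.json` path.
#' @param with_intensity Include the intensity raster (default TRUE when
#'   present).
#' @return `path`, invisibly.
#' @export
write_scene_json <- function(scene, path, with_intensity = TRUE) {
  stopifnot(inherits(scene, "fundus_scene"))
  obj <- list(
    od_ellipse = scene$od_ellipse,
    fovea = scene$fovea,
    vessels = lapply(scene$vessels, function(v) {
      list(points = unname(apply(v$points, 1, as.numeric, simplify = FALSE)),
           widths = v$widths, type = v$type, arcade = v$arcade)
    }),
    laterality = scene$laterality,
    ser = scene$ser,
    corneal_radius = scene$corneal_radius)
  if (with_intensity && !is.null(scene$intensity)) {
    obj$intensity <- list(grid = scene$intensity$grid,
                          origin = scene$intensity$origin)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fundus scene from JSON
#'
#' @param path A `.json` file written by [write_scene_json()] or following
#'   the same layout.
#' @return A [fundus_scene].
#' @export
read_scene_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vessels <- list()
  if (length(obj$vessels)) {
    raw <- obj$vessels
    if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
    vessels <- lapply(seq_along(raw), function(i) {
      v <- if (is.data.frame(obj$vessels)) {
        list(points = obj$vessels$points[[i]],
             widths = obj$vessels$widths[[i]],
             type = obj$vessels$type[[i]],
             arcade = obj$vessels$arcade[[i]])
      } else raw[[i]]
      pts <- v$points
      if (!is.matrix(pts)) pts <- do.call(rbind, lapply(pts, as.numeric))
      list(points = pts, widths = as.numeric(v$widths),
           type = v$type, arcade = v$arcade)
    })
  }
  intensity <- NULL
  if (!is.null(obj$intensity)) {
    intensity <- list(grid = as.matrix(obj$intensity$grid),
                      origin = as.numeric(obj$intensity$origin))
  }
  fundus_scene(
    od_ellipse = list(center = as.numeric(obj$od_ellipse$center),
                      semi_major = obj$od_ellipse$semi_major,
                      semi_minor = obj$od_ellipse$semi_minor,
                      angle = obj$od_ellipse$angle),
    fovea = as.numeric(obj$fovea), vessels = vessels, intensity = intensity,
    laterality = obj$laterality, ser = obj$ser %||% 0,
    corneal_radius = obj$corneal_radius %||% 7.8)
}
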