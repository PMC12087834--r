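#' Posterior eye volume from a binary mask
#'
#' Volume is the foreground voxel count times the voxel volume (product of
#' the spacing components), reported in mm^3.
#'
#' @param mask A [voxel_mask] with at least one foreground voxel.
#' @return Volume in mm^3.
#' @export
compute_volume <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  assert_nonempty(mask)
  n_foreground(mask) * prod(mask$spacing)
}

#' Fit an ellipsoid to a binary mask by principal component analysis
#'
#' The ellipsoid axes are the eigenvectors of the covariance matrix of the
#' foreground voxel-centre coordinates (in mm, spacing-scaled; population 1/N
#' normalisation), which allows free ellipsoidal rotation. Semidiameters use
#' the solid uniform ellipsoid moment relation: the variance along a
#' principal axis of a solid ellipsoid with semidiameter s is s^2/5, hence
#' s = sqrt(5 * eigenvalue). Each eigen-axis is assigned to the anatomical
#' axis with which its direction has maximal absolute dot product, and the
#' semidiameters are labelled `a` (anterior-posterior), `b` (nasal-temporal)
#' and `c` (inferior-superior) accordingly. For eigenvalue ties (a perfect
#' sphere) assignment falls back to the anatomical header order; a genuinely
#' ambiguous assignment (two distinct eigen-axes claiming one anatomical
#' label) is an error.
#'
#' With `label_axes = "none"` the anatomical assignment is skipped and the
#' principal axes are returned in descending-eigenvalue order with
#' semidiameters named `s1 >= s2 >= s3`; use this for eyes whose orientation
#' relative to the scanner frame is unknown or too oblique for a reliable
#' anatomical labelling.
#'
#' @param mask A [voxel_mask] with at least 30 non-coplanar foreground voxels.
#' @param label_axes `"anatomical"` (default) or `"none"`.
#' @return An object of class `ellipsoid`: list with `center` (mm), `axes`
#'   (3x3 matrix, unit columns named AP/NT/IS in grid mm space) and
#'   `semidiameters` (named vector `a`, `b`, `c` in mm); with
#'   `label_axes = "none"`, columns and semidiameters `s1`, `s2`, `s3` in
#'   descending size order.
#' @export
fit_ellipsoid <- function(mask, label_axes = c("anatomical", "none")) {
  label_axes <- match.arg(label_axes)
  stopifnot(inherits(mask, "voxel_mask"))
  assert_nonempty(mask)
  X <- foreground_coords_mm(mask)
  if (nrow(X) < 30) {
    stop("need at least 30 foreground voxels to fit an ellipsoid, got ", nrow(X))
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  S <- crossprod(Xc) / nrow(Xc)          # population covariance
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) <= 1e-10 * max(ev$values)) {
    stop("degenerate covariance (foreground effectively coplanar); ",
         "cannot fit a 3D ellipsoid")
  }
  semis <- sqrt(5 * ev$values)
  vecs <- ev$vectors

  if (label_axes == "none") {
    colnames(vecs) <- c("s1", "s2", "s3")
    return(structure(
      list(center = ctr, axes = vecs,
           semidiameters = c(s1 = semis[1], s2 = semis[2], s3 = semis[3])),
      class = "ellipsoid"))
  }

  # anatomical direction of each grid axis
  anat <- diag(3)
  colnames(anat) <- mask$axis_labels
  dots <- abs(t(vecs) %*% anat)          # eigen-axis x anatomical axis
  claim <- apply(dots, 1, which.max)
  if (anyDuplicated(claim)) {
    rel_spread <- (max(ev$values) - min(ev$values)) / max(ev$values)
    if (rel_spread < 1e-3) {
      claim <- seq_len(3)                # spherical tie: header order
    } else {
      dup <- colnames(anat)[claim[duplicated(claim)]]
      stop("ambiguous anatomical axis assignment: more than one principal ",
           "axis maps to ", paste(unique(dup), collapse = ", "))
    }
  }
  # reorder eigen system so columns follow AP, NT, IS
  lab_of_eigen <- colnames(anat)[claim]
  ord <- match(c("AP", "NT", "IS"), lab_of_eigen)
  axes <- vecs[, ord, drop = FALSE]
  semis <- semis[ord]
  # orient each axis along its anatomical direction; nasal-temporal sign
  # follows laterality (nasal flips between eyes)
  for (k in 1:3) {
    target <- anat[, match(c("AP", "NT", "IS")[k], colnames(anat))]
    s <- sign(sum(axes[, k] * target))
    if (k == 2 && mask$laterality == "left") s <- -s
    if (s != 0) axes[, k] <- axes[, k] * s
  }
  colnames(axes) <- c("AP", "NT", "IS")
  structure(
    list(center = ctr, axes = axes,
         semidiameters = c(a = semis[1], b = semis[2], c = semis[3])),
    class = "ellipsoid")
}

#' @export
print.ellipsoid <- function(x, ...) {
  s <- x$semidiameters
  cat("<ellipsoid>",
      paste(sprintf("%s = %.2f", names(s), s), collapse = ", "), "mm\n")
  invisible(x)
}

#' Horizontal and vertical asphericity of a fitted ellipsoid
#'
#' Asphericity is `Q_h = b^2/a^2 - 1` along the horizontal (nasal-temporal)
#' meridian and `Q_v = c^2/a^2 - 1` along the vertical (inferior-superior)
#' meridian. Zero means a perfect sphere along that meridian; negative
#' (relatively long anterior-posterior axis) is prolate, positive is oblate.
#'
#' @param e An `ellipsoid`, or a named numeric vector with elements `a`, `b`,
#'   `c` in mm.
#' @return Named numeric vector `c(Q_h = , Q_v = )`.
#' @export
compute_asphericity <- function(e) {
  s <- if (inherits(e, "ellipsoid")) e$semidiameters else e
  if (!all(c("a", "b", "c") %in% names(s))) {
    stop("need named semidiameters a, b, c")
  }
  if (any(s[c("a", "b", "c")] <= 0)) stop("semidiameters must be positive")
  c(Q_h = unname(s["b"]^2 / s["a"]^2 - 1),
    Q_v = unname(s["c"]^2 / s["a"]^2 - 1))
}

# boundary foreground voxels: foreground with at least one background
# 6-neighbour (grid edge counts as background)
boundary_indices <- function(grid) {
  d <- dim(grid)
  pad <- array(FALSE, dim = d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- grid
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  which(core & !nb, arr.ind = TRUE)
}

#' Radial RMS error between a fitted ellipsoid and a segmentation
#'
#' For every boundary foreground voxel (foreground with at least one
#' background 6-neighbour) the residual is the absolute difference between
#' the voxel-centre distance from the ellipsoid centre and the ellipsoid
#' surface radius along the same ray. The returned value is the root mean
#' square of these radial residuals, in mm. Radial distance is used because
#' the true point-to-ellipsoid distance has no closed form; the choice is
#' recorded in the result's `"definition"` attribute.
#'
#' @param mask A non-empty [voxel_mask].
#' @param e An `ellipsoid` from [fit_ellipsoid()].
#' @return RMS error in mm. If the ellipsoid centre lies outside the mask's
#'   bounding box the result carries attribute `center_outside = TRUE` and a
#'   warning is raised (not an error).
#' @export
rms_fit_error <- function(mask, e) {
  stopifnot(inherits(mask, "voxel_mask"), inherits(e, "ellipsoid"))
  assert_nonempty(mask)
  idx <- boundary_indices(mask$grid)
  P <- sweep(sweep(idx - 1, 2, mask$spacing, `*`), 2, e$center)
  r <- sqrt(rowSums(P^2))
  keep <- r > 0
  U <- P[keep, , drop = FALSE] / r[keep]
  # surface radius along u: t with || diag(1/s) t(A) (t u) || = 1
  W <- U %*% e$axes                      # components along principal axes
  s <- unname(e$semidiameters)           # positionally matched to axes columns
  t_surf <- 1 / sqrt((W[, 1] / s[1])^2 + (W[, 2] / s[2])^2 +
                     (W[, 3] / s[3])^2)
  rms <- sqrt(mean((r[keep] - t_surf)^2))
  box_lo <- (apply(which(mask$grid, arr.ind = TRUE), 2, min) - 1) * mask$spacing
  box_hi <- (apply(which(mask$grid, arr.ind = TRUE), 2, max) - 1) * mask$spacing
  if (any(e$center < box_lo) || any(e$center > box_hi)) {
    warning("ellipsoid centre lies outside the mask bounding region")
    attr(rms, "center_outside") <- TRUE
  }
  attr(rms, "definition") <- "radial residual over boundary voxels"
  rms
}

#' Dice overlap between two segmentations
#'
#' `2 |A intersect B| / (|A| + |B|)`; 1 indicates perfect overlap.
#'
#' @param mask_a,mask_b [voxel_mask] objects on identical grids (same shape
#'   and spacing).
#' @return Dice score in `[0, 1]`.
#' @export
dice_score <- function(mask_a, mask_b) {
  stopifnot(inherits(mask_a, "voxel_mask"), inherits(mask_b, "voxel_mask"))
  if (!identical(dim(mask_a$grid), dim(mask_b$grid))) {
    stop("masks have different grid shapes")
  }
  if (!isTRUE(all.equal(mask_a$spacing, mask_b$spacing))) {
    stop("masks have different voxel spacing")
  }
  na <- sum(mask_a$grid); nb <- sum(mask_b$grid)
  if (na + nb == 0) stop("Dice score undefined: both masks are empty")
  2 * sum(mask_a$grid & mask_b$grid) / (na + nb)
}

#' Intraclass correlation between two repeated measurement sessions
#'
#' Default is ICC(A,1): two-way, single measurement, absolute agreement
#' (subjects and raters/sessions both random, rater mean differences count
#' against agreement). `"consistency"` gives ICC(C,1), which ignores the
#' session main effect.
#'
#' @param x,y Paired measurements (session 1 and session 2), one value per
#'   eye; at least 3 complete pairs.
#' @param type `"agreement"` (ICC(A,1), default) or `"consistency"` (ICC(C,1)).
#' @return List with `icc`, `n` and `type`.
#' @export
icc_agreement <- function(x, y, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs, got ", n)
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  subj_means <- rowMeans(dat)
  sess_means <- colMeans(dat)
  ssr <- k * sum((subj_means - grand)^2)          # between subjects
  ssc <- n * sum((sess_means - grand)^2)          # between sessions
  sst <- sum((dat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (sst <= 0) stop("zero total variance: ICC undefined")
  icc <- if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  list(icc = icc, n = n, type = if (type == "agreement") "ICC(A,1)" else "ICC(C,1)")
}

#' Full shape metric set for one eye
#'
#' Convenience wrapper: fits the ellipsoid, computes volume, asphericity and
#' radial RMS error, and returns one tidy row.
#'
#' @param mask A [voxel_mask].
#' @param eye_id Identifier copied into the output row.
#' @return A one-row data.frame with columns `eye_id`, `a_mm`, `b_mm`, `c_mm`,
#'   `Q_h`, `Q_v`, `volume_mm3`, `rms_mm`.
#' @export
eye_shape_metrics <- function(mask, eye_id = "eye") {
  e <- fit_ellipsoid(mask)
  q <- compute_asphericity(e)
  data.frame(eye_id = eye_id,
             a_mm = unname(e$semidiameters["a"]),
             b_mm = unname(e$semidiameters["b"]),
             c_mm = unname(e$semidiameters["c"]),
             Q_h = q[["Q_h"]], Q_v = q[["Q_v"]],
             volume_mm3 = compute_volume(mask),
             rms_mm = as.numeric(rms_fit_error(mask, e)),
             stringsAsFactors = FALSE)
}
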