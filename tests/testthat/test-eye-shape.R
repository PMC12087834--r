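block_mask <- function(n = 10, spacing = c(1, 1, 1)) {
  g <- array(FALSE, dim = c(n + 4, n + 4, n + 4))
  g[3:(n + 2), 3:(n + 2), 3:(n + 2)] <- TRUE
  voxel_mask(g, spacing = spacing)
}

test_that("volume is foreground count times voxel volume", {
  expect_equal(compute_volume(block_mask(10)), 1000)
  expect_equal(compute_volume(block_mask(10, spacing = c(1.05, 1, 1))), 1050)
  empty <- voxel_mask(array(FALSE, dim = c(4, 4, 4)))
  expect_error(compute_volume(empty), "foreground")
})

test_that("PCA fit recovers axis-aligned and rotated ellipsoids", {
  truth <- c(10, 12, 11)
  m0 <- make_ellipsoid_mask(ellipsoid_spec(10, 12, 11, spacing = c(1, 1, 1)))
  e0 <- fit_ellipsoid(m0)
  expect_lt(max(abs(e0$semidiameters - truth) / truth), 0.03)
  # rotation invariance: 25 degrees about the inferior-superior axis
  m1 <- make_ellipsoid_mask(ellipsoid_spec(10, 12, 11, rotation = c(0, 0, 25),
                                           spacing = c(1, 1, 1)))
  e1 <- fit_ellipsoid(m1)
  expect_lt(max(abs(e1$semidiameters - e0$semidiameters) / e0$semidiameters),
            0.005)
  # axes are orthonormal
  expect_equal(unname(crossprod(e1$axes)), diag(3), tolerance = 1e-8)
})

test_that("a voxelised sphere fits with three equal semidiameters", {
  e <- fit_ellipsoid(make_ellipsoid_mask(
    ellipsoid_spec(12, 12, 12, spacing = c(1, 1, 1))))
  s <- e$semidiameters
  expect_lt((max(s) - min(s)) / mean(s), 0.01)
})

test_that("fit rejects degenerate and tiny inputs", {
  g <- array(FALSE, dim = c(10, 10, 10))
  g[2:9, 2:9, 5] <- TRUE                     # coplanar slab
  expect_error(fit_ellipsoid(voxel_mask(g)), "coplanar|degenerate")
  g2 <- array(FALSE, dim = c(10, 10, 10))
  g2[4:5, 4:5, 4:5] <- TRUE                  # 8 voxels
  expect_error(fit_ellipsoid(voxel_mask(g2)), "30")
})

test_that("scale equivariance: spacing scales volume k^3, semis k, Q unchanged", {
  spec1 <- ellipsoid_spec(10, 12, 11, spacing = c(1, 1, 1))
  m1 <- make_ellipsoid_mask(spec1)
  m2 <- voxel_mask(m1$grid, spacing = c(2, 2, 2))
  expect_equal(compute_volume(m2), 8 * compute_volume(m1))
  e1 <- fit_ellipsoid(m1); e2 <- fit_ellipsoid(m2)
  expect_equal(e2$semidiameters, 2 * e1$semidiameters, tolerance = 1e-10)
  expect_equal(compute_asphericity(e2), compute_asphericity(e1),
               tolerance = 1e-10)
})

test_that("asphericity formulas and sign convention", {
  expect_equal(compute_asphericity(c(a = 10, b = 10, c = 10)),
               c(Q_h = 0, Q_v = 0))
  expect_equal(compute_asphericity(c(a = 10, b = 11, c = 10.5)),
               c(Q_h = 0.21, Q_v = 0.1025))
  q <- compute_asphericity(c(a = 12, b = 11, c = 12))
  expect_equal(q[["Q_h"]], 121 / 144 - 1)
  expect_lt(q[["Q_h"]], 0)                 # prolate: long AP axis
  # ordering: for fixed b, c, increasing a strictly decreases both
  qs <- sapply(seq(9, 14, by = 0.5), function(a) {
    compute_asphericity(c(a = a, b = 11, c = 10))
  })
  expect_true(all(diff(qs["Q_h", ]) < 0))
  expect_true(all(diff(qs["Q_v", ]) < 0))
})

test_that("radial RMS error is small for self-fits and grows off-centre", {
  mask <- make_ellipsoid_mask(ellipsoid_spec(11, 12, 11.5, spacing = c(1, 1, 1)))
  e <- fit_ellipsoid(mask)
  rms0 <- rms_fit_error(mask, e)
  expect_lt(as.numeric(rms0), sqrt(3) / 2)   # below half the voxel diagonal
  shifted <- e
  shifted$center <- e$center + c(2, 0, 0)
  expect_gt(as.numeric(rms_fit_error(mask, shifted)), as.numeric(rms0))
})

test_that("RMS flags (but does not fail on) a centre outside the mask region", {
  mask <- make_ellipsoid_mask(ellipsoid_spec(10, 10, 10, spacing = c(1, 1, 1)))
  e <- fit_ellipsoid(mask)
  e$center <- e$center + c(100, 0, 0)
  expect_warning(r <- rms_fit_error(mask, e), "outside")
  expect_true(isTRUE(attr(r, "center_outside")))
})

test_that("Dice score: analytic cases, symmetry, errors", {
  g <- array(FALSE, dim = c(6, 6, 6))
  a <- g; a[1:2, 1:2, 1] <- TRUE             # 4 voxels
  b <- g; b[2:3, 1:2, 1] <- TRUE             # 4 voxels, overlap 2
  A <- voxel_mask(a); B <- voxel_mask(b)
  expect_identical(dice_score(A, A), 1)
  expect_identical(dice_score(A, B), 0.5)
  expect_identical(dice_score(A, B), dice_score(B, A))
  disj <- g; disj[5:6, 5:6, 6] <- TRUE
  expect_identical(dice_score(A, voxel_mask(disj)), 0)
  expect_error(dice_score(A, voxel_mask(array(TRUE, dim = c(3, 3, 3)))),
               "shape")
  expect_error(dice_score(voxel_mask(g), voxel_mask(g)), "empty")
})

test_that("ICC(A,1) behaves per its variance-component definition", {
  x <- c(10, 12, 14, 16, 18)
  expect_equal(icc_agreement(x, x)$icc, 1)
  set.seed(11)
  n <- 10000
  eye <- rnorm(n, sd = 1)
  r1 <- eye + rnorm(n, sd = 1)
  r2 <- eye + rnorm(n, sd = 1)
  expect_lt(abs(icc_agreement(r1, r2)$icc - 0.5), 0.02)  # absolute tolerance
  expect_lt(abs(icc_agreement(rnorm(n), rnorm(n))$icc), 0.05)
  expect_error(icc_agreement(rep(1, 5), rep(1, 5)), "variance")
  expect_error(icc_agreement(1:2, 1:2), "3")
})

test_that("ICC consistency form ignores a session offset, agreement does not", {
  set.seed(12)
  eye <- rnorm(500, sd = 1)
  r1 <- eye + rnorm(500, sd = 0.3)
  r2 <- eye + rnorm(500, sd = 0.3) + 1      # systematic session shift
  agree <- icc_agreement(r1, r2)$icc
  consist <- icc_agreement(r1, r2, type = "consistency")$icc
  expect_gt(consist, agree + 0.1)
})
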