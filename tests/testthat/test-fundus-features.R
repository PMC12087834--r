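test_that("magnification factor anchors at 1 and is monotone in myopia", {
  expect_equal(magnification_factor(0, 7.8), 1)
  expect_gt(magnification_factor(-6, 7.8), magnification_factor(0, 7.8))
  f <- sapply(seq(-12, 6, by = 2), magnification_factor)
  expect_true(all(diff(f) < 0))              # increasing SER shrinks factor
  expect_error(magnification_factor(-30), "range")
  expect_error(magnification_factor(0, 5), "range")
})

test_that("OD-fovea distance: 3-4-5 triangle, magnification, coincidence", {
  sc <- simple_scene(fovea = c(3, 4))
  expect_equal(od_fovea_distance(sc), 5)
  myopic <- simple_scene(fovea = c(3, 4), ser = -6)
  expect_equal(od_fovea_distance(myopic), 5 * magnification_factor(-6))
  expect_error(od_fovea_distance(simple_scene(fovea = c(0, 0))), "coincides")
  expect_error(od_fovea_angle(simple_scene(fovea = c(0, 0))), "coincides")
})

test_that("OD-fovea angle matches analytic geometry and harmonises laterality", {
  sc <- simple_scene(fovea = c(300, -15))
  expect_equal(od_fovea_angle(sc), atan2(-15, 300) * 180 / pi)
  expect_equal(od_fovea_angle(simple_scene(fovea = c(100, 0))), 0)
  right <- simple_scene(fovea = c(1, -1), laterality = "right")
  expect_equal(od_fovea_angle(right), -45)
  left <- simple_scene(fovea = c(-1, -1), laterality = "left")
  expect_equal(od_fovea_angle(left), -45)
})

test_that("OD metrics: area, ovality, orientation folding and circle tie-break", {
  circ <- simple_scene(semi_major = 10, semi_minor = 10, angle = 37)
  m <- od_metrics(circ)
  expect_equal(m[["od_area"]], 100 * pi)
  expect_equal(m[["od_ovality"]], 1)
  expect_equal(m[["od_orientation"]], 90)
  ell <- simple_scene(semi_major = 6, semi_minor = 4, angle = 0)
  m2 <- od_metrics(ell)
  expect_equal(m2[["od_area"]], pi * 24)
  expect_equal(m2[["od_ovality"]], 1.5)
  expect_equal(m2[["od_orientation"]], 0)
  rot <- simple_scene(semi_major = 6, semi_minor = 4, angle = 120)
  expect_equal(od_metrics(rot)[["od_orientation"]], 60)
})

test_that("CRAE/CRVE match the brute-force pairing oracle", {
  two <- simple_scene(vessels = list(
    straight_vessel(width = 10), straight_vessel(width = 10, from = c(0, 5))))
  expect_equal(crae(two), 0.88 * sqrt(200), tolerance = 1e-12)

  six_a <- simple_scene(vessels = lapply(1:6, function(i) {
    straight_vessel(width = 10, from = c(0, 3 * i))
  }))
  expect_equal(crae(six_a), oracle_pairing(rep(10, 6), 0.88),
               tolerance = 1e-9)
  six_v <- simple_scene(vessels = lapply(1:6, function(i) {
    straight_vessel(width = 10, from = c(0, 3 * i), type = "venule")
  }))
  expect_equal(crve(six_v), oracle_pairing(rep(10, 6), 0.95),
               tolerance = 1e-9)

  # distinct widths, odd counts, against the oracle
  for (w in list(c(12, 10, 9), c(15, 14, 13, 12, 11), runif(7, 8, 18))) {
    sc <- simple_scene(vessels = lapply(seq_along(w), function(i) {
      straight_vessel(width = w[i], from = c(0, 3 * i))
    }))
    expect_equal(crae(sc), oracle_pairing(sort(w, decreasing = TRUE)[1:min(6, length(w))], 0.88),
                 tolerance = 1e-9)
  }
  # no venules -> sentinel, not error
  expect_true(is.na(crve(two)))
})

test_that("CRAE never decreases when an input width increases", {
  set.seed(21)
  for (rep in 1:20) {
    w <- runif(6, 8, 18)
    sc1 <- simple_scene(vessels = lapply(1:6, function(i) {
      straight_vessel(width = w[i], from = c(0, 3 * i))
    }))
    j <- sample(6, 1)
    w2 <- w; w2[j] <- w2[j] + runif(1, 0, 4)
    sc2 <- simple_scene(vessels = lapply(1:6, function(i) {
      straight_vessel(width = w2[i], from = c(0, 3 * i))
    }))
    expect_gte(crae(sc2), crae(sc1))
  }
})

test_that("tortuosity: straight, semicircle, weighted pooling, zero chord", {
  straight <- simple_scene(vessels = list(straight_vessel(len = 10)))
  expect_equal(vessel_tortuosity(straight), 0)
  semi <- simple_scene(vessels = list(semicircle_vessel(radius = 10, n = 1000)))
  expect_equal(vessel_tortuosity(semi), pi / 2 - 1, tolerance = 1e-3)
  # arc length 10 each: semicircle radius 10/pi
  both <- simple_scene(vessels = list(
    straight_vessel(len = 10),
    semicircle_vessel(radius = 10 / pi, n = 2000)))
  expect_equal(vessel_tortuosity(both), 0.5 * (pi / 2 - 1), tolerance = 1e-3)
  loop <- mk_vessel(rbind(c(0, 0), c(1, 0), c(0, 0)))
  expect_warning(t <- vessel_tortuosity(simple_scene(vessels = list(
    straight_vessel(len = 10), loop))), "zero chord")
  expect_equal(t, 0)
})

test_that("box-counting dimension: line ~ 1, filled square ~ 2, sparse sentinel", {
  expect_equal(vessel_fd(line_map(512)), 1, tolerance = 0.05)
  expect_equal(vessel_fd(square_map(512, 256)), 2, tolerance = 0.1)
  expect_true(is.na(vessel_fd(matrix(0, 128, 128))))
  expect_error(vessel_fd(matrix(1, 32, 32)), "64")
  # agreement with the loop-based oracle on an irregular pattern
  set.seed(31)
  m <- matrix(runif(256^2) < 0.003, 256, 256)
  expect_equal(vessel_fd(m), oracle_fd(m), tolerance = 1e-10)
})

test_that("arcade concavity recovers exact and noisy parabola coefficients", {
  od <- c(0, 0); fovea <- c(300, 0)
  parab <- function(coef, noise_sd = 0, seed = NULL) {
    v <- seq(-200, 200, by = 5)
    u <- coef * v^2
    if (noise_sd > 0) {
      set.seed(seed)
      u <- u + rnorm(length(v), sd = noise_sd)
      v <- v + rnorm(length(v), sd = noise_sd)
    }
    mk_vessel(cbind(u, v), arcade = "superior-temporal")
  }
  sc <- simple_scene(fovea = fovea,
                     vessels = list(parab(0.05)))
  expect_equal(arcade_concavity(sc, "arteriole"), 0.05, tolerance = 1e-9)
  straight <- simple_scene(fovea = fovea, vessels = list(
    mk_vessel(cbind(seq(0, 100, 10), seq(0, 200, 20)),
              arcade = "superior-temporal")))
  expect_equal(arcade_concavity(straight, "arteriole"), 0, tolerance = 1e-12)
  # Monte-Carlo recovery with point noise SD 0.5 px
  errs <- sapply(1:100, function(s) {
    scn <- simple_scene(fovea = fovea,
                        vessels = list(parab(0.05, noise_sd = 0.5, seed = s)))
    arcade_concavity(scn, "arteriole") - 0.05
  })
  expect_lt(mean(abs(errs)), 0.01)
  # too few points -> sentinel
  few <- simple_scene(fovea = fovea, vessels = list(
    mk_vessel(rbind(c(0, 0), c(1, 1), c(2, 4)), arcade = "superior-temporal")))
  expect_true(is.na(arcade_concavity(few, "arteriole")))
})

test_that("foveal pixel intensity: uniform, boundary disc, border clipping", {
  unif <- simple_scene(fovea = c(50, 50), intensity = list(
    grid = matrix(100, 101, 101), origin = c(0, 0)))
  expect_equal(as.numeric(foveal_pixel_intensity(unif)), 100)
  # left half 0, right half 200, fovea on the dividing line
  g <- cbind(matrix(0, 101, 50), matrix(200, 101, 51))
  half <- simple_scene(fovea = c(50, 50),
                       intensity = list(grid = g, origin = c(0, 0)))
  expect_equal(as.numeric(foveal_pixel_intensity(half)), 100, tolerance = 6)
  border <- simple_scene(fovea = c(2, 50), intensity = list(
    grid = matrix(7, 101, 101), origin = c(0, 0)))
  out <- foveal_pixel_intensity(border)
  expect_equal(as.numeric(out), 7)
  expect_true(isTRUE(attr(out, "clipped")))
  expect_true(is.na(foveal_pixel_intensity(simple_scene())))
})

test_that("extract_features recovers generator ground truth across seeds", {
  for (seed in 1:25) {
    sc <- make_fundus_scene(seed = seed, waviness = 1,
                            od_fovea_ang = -5 - (seed %% 5),
                            arcade_coef = 0.004 + 0.0005 * (seed %% 4),
                            ser = c(-6, -2, 0, 2)[1 + seed %% 4])
    gt <- attr(sc, "ground_truth")$features
    fv <- extract_features(sc, fd_side = 256)
    expect_equal(fv$od_fovea_distance, gt$od_fovea_distance, tolerance = 1e-8)
    expect_equal(fv$od_fovea_angle, gt$od_fovea_angle, tolerance = 1e-8)
    expect_equal(fv$od_area, gt$od_area, tolerance = 1e-8)
    expect_equal(fv$od_orientation, gt$od_orientation, tolerance = 1e-8)
    expect_equal(fv$od_ovality, gt$od_ovality, tolerance = 1e-8)
    expect_equal(fv$crae, gt$crae, tolerance = 1e-8)
    expect_equal(fv$crve, gt$crve, tolerance = 1e-8)
    expect_equal(fv$arterial_concavity, gt$arterial_concavity,
                 tolerance = 0.002)
    expect_equal(fv$venous_concavity, gt$venous_concavity, tolerance = 0.002)
    expect_equal(fv$fpi, gt$fpi)
    expect_gt(fv$tortuosity, 0)
    expect_true(fv$fd > 0.9 && fv$fd < 2)
  }
})

test_that("mirrored left/right scene pairs give identical features", {
  r <- make_fundus_scene(seed = 5, waviness = 2, laterality = "right")
  l <- make_fundus_scene(seed = 5, waviness = 2, laterality = "left")
  fr <- extract_features(r, fd_side = 256)
  fl <- extract_features(l, fd_side = 256)
  for (nm in setdiff(fundus_feature_names(), "fd")) {
    expect_equal(fl[[nm]], fr[[nm]], tolerance = 1e-6, label = nm)
  }
  # box counting is anchored at one raster corner, so mirroring can move a
  # few boundary boxes; the dimension itself must still agree closely
  expect_equal(fl$fd, fr$fd, tolerance = 0.02)
})

test_that("homogeneity: scaling coordinates scales distances, not shape ratios", {
  sc <- make_fundus_scene(seed = 9, waviness = 1, with_intensity = FALSE)
  f <- 2.5
  scale_scene <- function(s, f) {
    s$od_ellipse$center <- s$od_ellipse$center * f
    s$od_ellipse$semi_major <- s$od_ellipse$semi_major * f
    s$od_ellipse$semi_minor <- s$od_ellipse$semi_minor * f
    s$fovea <- s$fovea * f
    s$vessels <- lapply(s$vessels, function(v) {
      v$points <- v$points * f
      v$widths <- v$widths * f
      v
    })
    s
  }
  a <- extract_features(sc, fd_side = 256)
  b <- extract_features(scale_scene(sc, f), fd_side = 256)
  expect_equal(b$od_fovea_distance, f * a$od_fovea_distance)
  expect_equal(b$od_area, f^2 * a$od_area)
  expect_equal(b$crae, f * a$crae)
  expect_equal(b$od_fovea_angle, a$od_fovea_angle)
  expect_equal(b$od_ovality, a$od_ovality)
  expect_equal(b$tortuosity, a$tortuosity, tolerance = 1e-10)
  expect_equal(b$arterial_concavity, a$arterial_concavity / f,
               tolerance = 1e-12)
})

test_that("scene JSON round trip preserves features", {
  sc <- make_fundus_scene(seed = 13, waviness = 1, with_intensity = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_scene_json(sc, path)
  back <- read_scene_json(path)
  expect_equal(extract_features(back, fd_side = 128),
               extract_features(sc, fd_side = 128), tolerance = 1e-10)
})
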