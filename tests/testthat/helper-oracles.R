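# Independent oracles, deliberately written without reference to the package
# implementations they check.

# Brute-force big-six pairing: recursive, index-based, no vectorised tricks.
oracle_pairing <- function(widths, k) {
  if (length(widths) == 1) return(widths)
  w <- sort(widths)                       # ascending
  n <- length(w)
  survivors <- c()
  if (n %% 2 == 1) {
    mid <- (n + 1) / 2
    survivors <- w[mid]
    w <- w[-mid]
    n <- n - 1
  }
  for (i in seq_len(n / 2)) {
    lo <- w[i]
    hi <- w[n - i + 1]
    survivors <- c(survivors, k * sqrt(lo^2 + hi^2))
  }
  oracle_pairing(survivors, k)
}

# Box counting by explicit block loops.
oracle_box_count <- function(map, size) {
  nr <- nrow(map); nc <- ncol(map)
  count <- 0L
  for (r0 in seq(1, nr, by = size)) {
    for (c0 in seq(1, nc, by = size)) {
      blk <- map[r0:min(nr, r0 + size - 1), c0:min(nc, c0 + size - 1)]
      if (any(blk)) count <- count + 1L
    }
  }
  count
}

oracle_fd <- function(map) {
  side <- min(dim(map))
  sizes <- 2^(seq(floor(log2(side / 4)), 1))
  counts <- sapply(sizes, function(s) oracle_box_count(map, s))
  unname(coef(lm(log(counts) ~ log(1 / sizes)))[2])
}

# straight-line mask helpers used by FD tests
line_map <- function(side = 512) {
  m <- matrix(FALSE, side, side)
  m[side %/% 2, ] <- TRUE
  m
}

square_map <- function(side = 512, fill = 256) {
  m <- matrix(FALSE, side, side)
  lo <- (side - fill) %/% 2 + 1
  m[lo:(lo + fill - 1), lo:(lo + fill - 1)] <- TRUE
  m
}

# Independent rotation-matrix oracle (same x-then-y-then-z convention as the
# generator, coded via axis-angle products rather than explicit matrices).
oracle_rotation <- function(angles_deg) {
  axis_rot <- function(axis, theta) {
    K <- matrix(0, 3, 3)
    K[c(6, 8)] <- c(1, -1) * (axis == 1)
    K[c(7, 3)] <- c(1, -1) * (axis == 2)
    K[c(2, 4)] <- c(1, -1) * (axis == 3)
    diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  }
  th <- angles_deg * pi / 180
  axis_rot(3, th[3]) %*% axis_rot(2, th[2]) %*% axis_rot(1, th[1])
}

# match fitted principal axes to the known true (rotated) axes by greedy
# maximal |dot|, returning fitted semidiameters in true-axis order
match_semis_to_truth <- function(fit, R_true) {
  out <- numeric(3)
  used <- logical(3)
  for (k in 1:3) {
    d <- abs(as.numeric(t(fit$axes) %*% R_true[, k]))
    d[used] <- -Inf
    j <- which.max(d)
    used[j] <- TRUE
    out[k] <- fit$semidiameters[j]
  }
  out
}

with_seed_shuffle <- function(x, seed) {
  set.seed(seed)
  sample(x)
}

# minimal scene builders
simple_scene <- function(fovea = c(300, -15), laterality = "right", ser = 0,
                         vessels = list(), od = c(0, 0), intensity = NULL,
                         semi_major = 10, semi_minor = 10, angle = 0) {
  fundus_scene(
    od_ellipse = list(center = od, semi_major = semi_major,
                      semi_minor = semi_minor, angle = angle),
    fovea = fovea, vessels = vessels, intensity = intensity,
    laterality = laterality, ser = ser)
}

mk_vessel <- function(points, width = 10, type = "arteriole",
                      arcade = "other") {
  list(points = points, widths = rep(width, nrow(points)), type = type,
       arcade = arcade)
}

straight_vessel <- function(len = 10, width = 10, type = "arteriole",
                            from = c(0, 0), dir = c(1, 0), n = 11) {
  tt <- seq(0, len, length.out = n)
  mk_vessel(cbind(from[1] + tt * dir[1], from[2] + tt * dir[2]),
            width = width, type = type)
}

semicircle_vessel <- function(radius = 10, n = 1000, width = 10,
                              type = "arteriole") {
  th <- seq(0, pi, length.out = n)
  mk_vessel(cbind(radius * cos(th), radius * sin(th)), width = width,
            type = type)
}
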