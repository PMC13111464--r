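make_cylinder <- function(d = 8, h = 200, n = 3000, sigma = 0.1, seed = 1,
                          tilt = 0, half = FALSE, offset = c(0, 0, 0)) {
  withr::with_seed(seed, {
    th <- if (half) runif(n, pi / 2, 3 * pi / 2) else runif(n, 0, 2 * pi)
    z <- runif(n, 0, h)
    pts <- cbind(d / 2 * cos(th), d / 2 * sin(th), z) +
      matrix(rnorm(3 * n, sd = sigma), ncol = 3)
  })
  if (tilt != 0) {
    R <- rbind(c(1, 0, 0), c(0, cos(tilt), -sin(tilt)),
               c(0, sin(tilt), cos(tilt)))
    pts <- pts %*% t(R)
  }
  sweep(pts, 2, offset, `+`)
}

test_that("slicing extracts the base-relative height window", {
  cyl <- make_cylinder(seed = 2)
  base <- min(cyl[, 3])
  slab <- slice_at_height(cyl, stem_diameter_config())
  expect_true(all(slab[, 3] >= base + 7.5 - 1e-9 &
                  slab[, 3] <= base + 12.5 + 1e-9))
  expect_equal(nrow(slab),
               sum(cyl[, 3] >= base + 7.5 & cyl[, 3] <= base + 12.5))
  # base offset: same slab relative to the base
  off <- make_cylinder(seed = 2, offset = c(0, 0, 500))
  slab2 <- slice_at_height(off, stem_diameter_config())
  expect_equal(nrow(slab2), nrow(slab))
  expect_equal(slab2[, 3] - 500, slab[, 3])
  # slab thicker than the stem: everything retained
  all_of_it <- slice_at_height(cyl, stem_diameter_config(
    height_mm = 100, slab_half_thickness_mm = 300))
  expect_equal(nrow(all_of_it), nrow(cyl))
  expect_error(slice_at_height(cyl, stem_diameter_config(height_mm = 1e5)),
               "slab")
})

test_that("OBB recovers orientation with orthogonal rotation matrices", {
  withr::with_seed(4, box <- cbind(runif(5000, -4, 4), runif(5000, -2, 2),
                                   runif(5000, -1, 1)))
  obb <- compute_obb(box)
  expect_lt(max(abs(crossprod(obb$rotation) - diag(3))), 1e-9)
  expect_equal(det(obb$rotation), 1, tolerance = 1e-9)
  expect_lt(max(abs(abs(obb$rotation) - diag(3))), 0.05)  # near-axis-aligned
  # known rotation: volume recovered, axes align up to sign/permutation
  th <- 0.6
  R0 <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  obb2 <- compute_obb(box %*% t(R0))
  expect_equal(prod(obb2$half_extents), prod(obb$half_extents),
               tolerance = 1e-6)
  align <- abs(t(R0 %*% obb$rotation) %*% obb2$rotation)
  expect_equal(apply(align, 1, max), rep(1, 3), tolerance = 1e-6)
  expect_error(compute_obb(cbind(1:5, 2 * (1:5), 3 * (1:5))), "collinear")
})

test_that("OBB volume never exceeds the axis-aligned bounding box volume", {
  for (seed in 1:50) {
    pts <- withr::with_seed(seed, matrix(rnorm(150), ncol = 3) %*%
                              matrix(runif(9, -1, 1), 3, 3))
    obb <- compute_obb(pts)
    aabb <- prod(apply(pts, 2, function(v) diff(range(v))))
    expect_lte(8 * prod(obb$half_extents), aabb * (1 + 1e-9))
    # all points inside the box (expanded by a hair)
    local <- sweep(pts, 2, obb$center) %*% obb$rotation
    expect_true(all(abs(local) <= rep(obb$half_extents, each = nrow(local)) +
                      1e-6))
  }
})

test_that("OBB alignment maps the principal axis to the first coordinate", {
  slab <- slice_at_height(make_cylinder(tilt = 20 * pi / 180, seed = 6),
                          stem_diameter_config(slab_half_thickness_mm = 2.5))
  obb <- compute_obb(slab)
  aligned <- align_with_obb(slab, obb)
  v <- apply(aligned, 2, stats::var)
  expect_true(which.max(v) == 1L)
  # applying R then its transpose restores the centered points
  back <- aligned %*% t(obb$rotation)
  expect_lt(max(abs(back - sweep(slab, 2, obb$center))), 1e-9)
})

test_that("circle fitting solves the worked example and exact circles", {
  cf <- fit_circle(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)))
  expect_equal(unname(cf$center), c(1, 1), tolerance = 1e-12)
  expect_equal(cf$radius, sqrt(2), tolerance = 1e-12)
  expect_equal(cf$rms_residual, 0, tolerance = 1e-9)
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  exact <- cbind(3 + 5 * cos(th), -2 + 5 * sin(th))
  cf2 <- fit_circle(exact)
  expect_equal(unname(cf2$center), c(3, -2), tolerance = 1e-9)
  expect_equal(cf2$radius, 5, tolerance = 1e-9)
  expect_error(fit_circle(cbind(1:5, 2 * (1:5))), "collinear")
})

test_that("circle fit matches a brute-force minimizer of the squared objective", {
  withr::with_seed(8, {
    th <- runif(200, 0, 2 * pi)
    r <- 5 + rnorm(200, sd = 0.1)
    pts <- cbind(1 + r * cos(th), -3 + r * sin(th))
  })
  cf <- fit_circle(pts)
  expect_equal(cf$radius, 5, tolerance = 0.02 * 5)
  obj <- function(p) sum(((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 -
                            p[3]^2)^2)
  # oracle: dense grid + Nelder-Mead descent on the printed objective
  grid <- expand.grid(a = seq(0, 2, by = 0.1), b = seq(-4, -2, by = 0.1),
                      r = seq(4.5, 5.5, by = 0.05))
  st <- grid[which.min(apply(grid, 1, obj)), ]
  ref <- stats::optim(as.numeric(st), obj,
                      control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(obj(c(cf$center, cf$radius)), ref$value,
               tolerance = 1e-4 * max(1, ref$value))
  expect_equal(unname(c(cf$center, cf$radius)), ref$par, tolerance = 1e-3)
})

test_that("stem diameter recovers ground truth across geometries", {
  # vertical full-view cylinder, sigma = 0.1: within 2%
  est <- stem_diameter(make_cylinder(d = 8, seed = 10))
  expect_lt(abs(est$diameter_mm - 8) / 8, 0.02)
  # tilted 20 degrees: OBB correction path, within 5%
  est_t <- stem_diameter(make_cylinder(d = 8, tilt = 20 * pi / 180, seed = 11))
  expect_lt(abs(est_t$diameter_mm - 8) / 8, 0.05)
  # half-cylinder single-view visibility: within 10% (documented bias)
  est_h <- stem_diameter(make_cylinder(d = 8, half = TRUE, seed = 12))
  expect_lt(abs(est_h$diameter_mm - 8) / 8, 0.10)
})

test_that("stem diameter is monotone in truth and rigid-motion stable", {
  ds <- c(4, 6, 8, 10, 12)
  est <- vapply(seq_along(ds), function(i)
    stem_diameter(make_cylinder(d = ds[i], seed = 20 + i))$diameter_mm,
    numeric(1))
  expect_true(all(diff(est) > 0))
  cyl <- make_cylinder(d = 8, seed = 30)
  d0 <- stem_diameter(cyl)$diameter_mm
  rotz <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                            c(0, 0, 1))
  moved <- sweep(cyl %*% t(rotz(1.1)), 2, c(250, -80, 40), `+`)
  expect_lt(abs(stem_diameter(moved)$diameter_mm - d0) / d0, 0.01)
})
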