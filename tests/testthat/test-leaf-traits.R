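test_that("projection drops the orthogonal coordinate, order preserved", {
  pts <- rbind(c(1, 2, 3), c(4, 5, 6))
  expect_equal(project(pts, "XOY"), pts[, 1:2])
  expect_equal(project(pts, "YOZ"), pts[, 2:3])
  expect_equal(project(pts, "XOZ"), pts[, c(1, 3)])
  expect_equal(nrow(project(matrix(rnorm(300), ncol = 3), "XOY")), 100L)
})

test_that("polynomial fitting is exact on polynomial data", {
  x <- seq(-3, 5, by = 0.5)
  lin <- fit_polynomial(cbind(x, 2 * x + 1), degree = 1)
  expect_equal(lin$coefficients, c(1, 2), tolerance = 1e-10)
  expect_lt(lin$rss, 1e-18)
  quad <- fit_polynomial(cbind(x, x^2), degree = 2)
  expect_equal(quad$coefficients, c(0, 0, 1), tolerance = 1e-9)
  expect_lt(quad$rss, 1e-16)
  expect_error(fit_polynomial(cbind(rep(1, 5), 1:5), degree = 1),
               "rank-deficient")
  expect_error(fit_polynomial(cbind(c(1, 2), c(1, 2)), degree = 3),
               "distinct")
})

test_that("noisy-line fit matches a brute-force least-squares oracle", {
  withr::with_seed(19, {
    x <- runif(80, 0, 10)
    y <- 3 * x - 2 + rnorm(80, sd = 0.5)
  })
  fit <- fit_polynomial(cbind(x, y), degree = 1)
  expect_equal(fit$coefficients[2], 3, tolerance = 3 * 0.5 / sqrt(80) * 3)
  # oracle: coarse grid + local refinement over (a0, a1)
  sse <- function(p) sum((y - p[1] - p[2] * x)^2)
  grid <- expand.grid(a0 = seq(-4, 0, by = 0.05), a1 = seq(2, 4, by = 0.05))
  best <- grid[which.min(apply(grid, 1, sse)), ]
  ref <- stats::optim(as.numeric(best), sse)$value
  expect_equal(fit$rss, ref, tolerance = 1e-6)
})

test_that("residual sum of squares is non-increasing in the degree", {
  withr::with_seed(23, {
    x <- runif(60, 0, 5)
    y <- sin(x) + rnorm(60, sd = 0.1)
  })
  rss <- vapply(1:6, function(m)
    fit_polynomial(cbind(x, y), degree = m)$rss, numeric(1))
  expect_true(all(diff(rss) <= 1e-9))
})

test_that("intersecting extrusions reconstructs known space curves", {
  # both fits constant zero: the segment of the shared axis
  y <- seq(0, 10, by = 0.5)
  f0 <- fit_polynomial(cbind(y, 0 * y), degree = 1, indep = "y")
  c0 <- intersect_extrusions(f0, f0)
  expect_equal(c0$arc_length_mm, 10, tolerance = 1e-10)
  # f_xoy = y, f_yoz = 0: the 45-degree line in the XOY plane
  f1 <- fit_polynomial(cbind(y, y), degree = 1, indep = "y")
  c1 <- intersect_extrusions(f1, f0)
  expect_equal(c1$arc_length_mm, 10 * sqrt(2), tolerance = 1e-9)
  # known cubic space curve, noiseless sampling
  fy <- seq(-2, 2, by = 0.1)
  fx <- 0.3 * fy^3 - fy
  fz <- 0.5 * fy^2 + 2 * fy
  cx <- fit_polynomial(cbind(fy, fx), degree = 3, indep = "y")
  cz <- fit_polynomial(cbind(fy, fz), degree = 3, indep = "y")
  sc <- intersect_extrusions(cx, cz)
  tt <- seq(-2, 2, length.out = 101)
  pts <- phenopoint:::curve_points(sc, tt)
  expect_lt(max(abs(pts - cbind(0.3 * tt^3 - tt, tt, 0.5 * tt^2 + 2 * tt))),
            1e-6)
  # disjoint domains are rejected
  g1 <- fit_polynomial(cbind(0:5, 0:5), degree = 1, indep = "y")
  g2 <- fit_polynomial(cbind(10:15, 10:15), degree = 1, indep = "y")
  expect_error(intersect_extrusions(g1, g2), "overlap")
})

test_that("arc length reproduces closed forms", {
  seg <- space_curve(c(0, 3), c(0, 4), c(0, 0), domain = c(0, 1))
  expect_equal(seg$arc_length_mm, 5)  # 3-4-5 triangle
  circ <- space_curve(x = function(t) cos(t), y = function(t) sin(t),
                      z = function(t) 0 * t, domain = c(0, 2 * pi),
                      dx = function(t) -sin(t), dy = function(t) cos(t),
                      dz = function(t) 0 * t)
  expect_equal(circ$arc_length_mm, 2 * pi, tolerance = 1e-9)
  par <- space_curve(c(0, 1), c(0, 0, 1), c(0), domain = c(0, 1))
  expect_equal(par$arc_length_mm, sqrt(5) / 2 + asinh(2) / 4,
               tolerance = 1e-9)
  expect_error(space_curve(c(0, 1), c(0), c(0), domain = c(1, 1)), "a < b")
})

test_that("arc length converges under subinterval doubling and bounds chords", {
  sc <- space_curve(c(0, 2, -1, 0.3), c(0, 1), c(1, 0, 0.5),
                    domain = c(-1, 2), subintervals = 100L)
  L1 <- arc_length(sc, subintervals = 1000L)
  L2 <- arc_length(sc, subintervals = 2000L)
  expect_lt(abs(L2 - L1) / L2, 1e-8)
  ends <- phenopoint:::curve_points(sc, sc$domain)
  expect_gte(sc$arc_length_mm, sqrt(sum((ends[2, ] - ends[1, ])^2)))
  # equality for affine curves (degree-1 fits)
  lin <- space_curve(c(0, 1), c(0, 2), c(0, 3), domain = c(0, 4))
  pe <- phenopoint:::curve_points(lin, lin$domain)
  expect_equal(lin$arc_length_mm, sqrt(sum((pe[2, ] - pe[1, ])^2)),
               tolerance = 1e-10)
})

test_that("leaf length recovers a flat band and known midribs", {
  # flat rectangular band, 120 mm along y
  withr::with_seed(31, {
    t <- runif(2000)
    s <- runif(2000, -8, 8)
  })
  band <- cbind(s, 120 * t, 0 * t)
  res <- leaf_length(band)
  expect_equal(res$length_mm, 120, tolerance = 0.5)
  # noiseless curved leaf on a cubic midrib: relative error < 1e-3
  # (endpoints included so the observed domain spans the full midrib;
  # fitting frame = generating frame, so the midrib is exactly cubic)
  t2 <- c(0, 1, t[-(1:2)])
  mid <- cbind(0 * t2, 100 * t2, 20 * t2^2 - 10 * t2^3) +
    cbind(s, 0 * t2, 0 * t2)
  truth <- phenopoint:::simpson_quadrature(
    function(u) sqrt(100^2 + (40 * u - 30 * u^2)^2), 0, 1, 1e5)
  res2 <- leaf_length(mid, leaf_length_config(prealign = FALSE))
  expect_lt(abs(res2$length_mm - truth) / truth, 1e-3)
})

test_that("leaf length tolerates sensor noise and rigid motion", {
  lens <- vapply(1:20, function(i) {
    pl <- generate_plant(plant_spec(leaf_count = 1, leaf_length_mm = 100,
                                    leaf_arch_mm = 40, noise_sigma_mm = 1,
                                    seed = 100 + i))
    leaf <- pl$cloud[pl$cloud$labels == 2L]
    abs(leaf_length(leaf)$length_mm - pl$truth$leaf_lengths_mm[1]) /
      pl$truth$leaf_lengths_mm[1]
  }, numeric(1))
  expect_lt(stats::median(lens), 0.05)
  # rigid rotation + translation changes the estimate by < 1%
  pl <- generate_plant(plant_spec(leaf_count = 1, noise_sigma_mm = 0.5,
                                  seed = 55))
  leaf <- pl$cloud[pl$cloud$labels == 2L]
  L0 <- leaf_length(leaf)$length_mm
  th <- 0.7; R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0),
                        c(0, 0, 1))
  R2 <- rbind(c(1, 0, 0), c(0, cos(0.4), -sin(0.4)), c(0, sin(0.4), cos(0.4)))
  moved <- leaf
  moved$coords <- sweep(leaf$coords %*% t(R2 %*% R), 2, c(100, -50, 30), `+`)
  L1 <- leaf_length(moved)$length_mm
  expect_lt(abs(L1 - L0) / L0, 0.01)
})
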