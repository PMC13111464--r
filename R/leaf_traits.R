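# Leaf length from a single-view leaf point cloud: project onto two
# orthogonal planes sharing the leaf's long axis, fit a polynomial to each
# projection by least squares, intersect the two extruded surfaces into a
# parametric space curve, and integrate its arc length.

# Composite Simpson quadrature of f over [a, b] with n subintervals (n made
# even). Kept as an explicit primitive: the arc-length contract pins the rule.
simpson_quadrature <- function(f, a, b, n = 1000L) {
  n <- as.integer(n)
  if (n %% 2L == 1L) n <- n + 1L
  h <- (b - a) / n
  t <- seq(a, b, length.out = n + 1L)
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  sum(w * f(t)) * h / 3
}

polymul <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p))
    out[i:(i + length(q) - 1L)] <- out[i:(i + length(q) - 1L)] + p[i] * q
  out
}

polyval <- function(coef, t) {
  # Horner; coef = c(a0, a1, ..., am)
  out <- rep(coef[length(coef)], length(t))
  for (j in rev(seq_len(length(coef) - 1L))) out <- out * t + coef[j]
  out
}

polyderiv <- function(coef) {
  if (length(coef) <= 1L) return(0)
  coef[-1L] * seq_len(length(coef) - 1L)
}

#' Project points onto a coordinate plane
#'
#' Drops the coordinate orthogonal to the plane; point order is preserved.
#'
#' @param points n x 3 coordinate matrix or a `point_cloud`.
#' @param plane `"XOY"`, `"YOZ"` or `"XOZ"`.
#' @return n x 2 matrix with the plane's two coordinates, in axis order.
#' @export
project <- function(points, plane = c("XOY", "YOZ", "XOZ")) {
  if (inherits(points, "point_cloud")) points <- points$coords
  plane <- match.arg(plane)
  if (nrow(points) == 0L) stop("empty point set")
  cols <- switch(plane, XOY = c(1L, 2L), YOZ = c(2L, 3L), XOZ = c(1L, 3L))
  points[, cols, drop = FALSE]
}

#' Least-squares polynomial fit of a planar projection
#'
#' Fits dep = a0 + a1 t + ... + am t^m by minimizing the sum of squared
#' errors (the normal equations of the least-squares objective). The
#' independent variable is centered and scaled internally for conditioning;
#' coefficients are reported in original units. The residual sum of squares
#' at the solution and the observed fit domain are carried on the result.
#'
#' @param points2d n x 2 matrix, column 1 = independent variable, column 2 =
#'   dependent variable.
#' @param degree polynomial degree m >= 1.
#' @param indep,dep axis names recorded on the result (documentation only).
#' @return object of class `polynomial_curve`: `coefficients` (a0..am),
#'   `degree`, `indep`, `dep`, `domain`, `rss`.
#' @export
fit_polynomial <- function(points2d, degree = 3L, indep = "t", dep = "v") {
  points2d <- as.matrix(points2d)
  stopifnot(degree >= 1L, ncol(points2d) == 2L)
  t <- points2d[, 1L]; v <- points2d[, 2L]
  if (length(unique(t)) < degree + 1L)
    stop(sprintf(
      "rank-deficient design: need >= %d distinct independent values, have %d",
      degree + 1L, length(unique(t))))
  mu <- mean(t); sdv <- stats::sd(t)
  if (sdv == 0) stop("rank-deficient design: constant independent variable")
  u <- (t - mu) / sdv
  X <- outer(u, 0:degree, `^`)
  fit <- stats::lm.fit(X, v)
  if (fit$rank < degree + 1L)
    stop("rank-deficient design: collinear polynomial basis")
  b <- fit$coefficients
  # compose p(u) with u = (t - mu)/sd to get coefficients in original units
  lin <- c(-mu / sdv, 1 / sdv)
  coef <- c(b[1L], numeric(degree))
  pw <- 1
  for (j in seq_len(degree)) {
    pw <- polymul(pw, lin)
    coef[seq_along(pw)] <- coef[seq_along(pw)] + b[j + 1L] * pw
  }
  structure(list(coefficients = unname(coef), degree = as.integer(degree),
                 indep = indep, dep = dep, domain = range(t),
                 rss = sum(fit$residuals^2)),
            class = "polynomial_curve")
}

#' Evaluate a fitted polynomial curve
#' @param object a `polynomial_curve`.
#' @param t values of the independent variable.
#' @param ... unused.
#' @return predicted dependent values.
#' @export
predict.polynomial_curve <- function(object, t, ...) {
  polyval(object$coefficients, t)
}

#' Parametric space curve
#'
#' r(t) = (x(t), y(t), z(t)) over \[a, b\], either polynomial (coefficient
#' vectors, analytic derivatives) or functional (component functions and
#' their derivatives supplied directly). The arc length is computed at
#' construction by [arc_length()].
#'
#' @param x,y,z polynomial coefficient vectors (a0..am) or functions of t.
#' @param dx,dy,dz derivative functions (required iff the components are
#'   functions).
#' @param domain length-2 parameter interval `c(a, b)`, a < b.
#' @param subintervals Simpson subintervals for the stored arc length.
#' @return object of class `space_curve` with field `arc_length_mm`.
#' @export
space_curve <- function(x, y, z, domain, dx = NULL, dy = NULL, dz = NULL,
                        subintervals = 1000L) {
  stopifnot(length(domain) == 2L)
  if (domain[1L] >= domain[2L]) stop("domain must satisfy a < b")
  functional <- is.function(x)
  if (functional && (is.null(dx) || is.null(dy) || is.null(dz)))
    stop("functional components require derivative functions dx, dy, dz")
  sc <- structure(list(x = x, y = y, z = z, dx = dx, dy = dy, dz = dz,
                       functional = functional, domain = as.numeric(domain),
                       arc_length_mm = NA_real_),
                  class = "space_curve")
  sc$arc_length_mm <- arc_length(sc, subintervals = subintervals)
  sc
}

curve_points <- function(curve, t) {
  if (curve$functional)
    cbind(curve$x(t), curve$y(t), curve$z(t))
  else
    cbind(polyval(curve$x, t), polyval(curve$y, t), polyval(curve$z, t))
}

#' Arc length of a space curve
#'
#' Composite Simpson quadrature of the speed sqrt(x'(t)^2 + y'(t)^2 +
#' z'(t)^2) over the parameter domain, with derivatives taken analytically
#' from the polynomial coefficients (or from the supplied derivative
#' functions). The subinterval count is doubled until the estimate changes by
#' less than 1e-10 relative (at most six doublings).
#'
#' @param curve a [space_curve()].
#' @param subintervals starting subinterval count (>= 10).
#' @return length in mm.
#' @export
arc_length <- function(curve, subintervals = 1000L) {
  stopifnot(inherits(curve, "space_curve"), subintervals >= 10L)
  a <- curve$domain[1L]; b <- curve$domain[2L]
  if (a >= b) stop("domain must satisfy a < b")
  speed <- if (curve$functional) {
    function(t) sqrt(curve$dx(t)^2 + curve$dy(t)^2 + curve$dz(t)^2)
  } else {
    dx <- polyderiv(curve$x); dy <- polyderiv(curve$y); dz <- polyderiv(curve$z)
    function(t) sqrt(polyval(dx, t)^2 + polyval(dy, t)^2 + polyval(dz, t)^2)
  }
  n <- as.integer(subintervals)
  L <- simpson_quadrature(speed, a, b, n)
  for (i in 1:6) {
    n <- 2L * n
    L2 <- simpson_quadrature(speed, a, b, n)
    if (abs(L2 - L) <= 1e-10 * max(abs(L2), 1e-12)) return(L2)
    L <- L2
  }
  L
}

#' Intersect two extruded fitted curves into a space curve
#'
#' Both planar fits must share the same independent axis (the leaf's long
#' axis, conventionally y). Extruding the XOY fit along z and the YOZ fit
#' along x gives two surfaces whose intersection is the parametric curve
#' r(y) = (f_xoy(y), y, f_yoz(y)) over the overlap of the two fit domains.
#'
#' @param curve_xoy `polynomial_curve` predicting x from the shared axis.
#' @param curve_yoz `polynomial_curve` predicting z from the shared axis.
#' @param subintervals Simpson subintervals for the arc length.
#' @return a [space_curve()] parameterized by the shared axis.
#' @export
intersect_extrusions <- function(curve_xoy, curve_yoz, subintervals = 1000L) {
  stopifnot(inherits(curve_xoy, "polynomial_curve"),
            inherits(curve_yoz, "polynomial_curve"))
  if (!identical(curve_xoy$indep, curve_yoz$indep))
    stop("the two fits must share the same independent axis")
  dom <- c(max(curve_xoy$domain[1L], curve_yoz$domain[1L]),
           min(curve_xoy$domain[2L], curve_yoz$domain[2L]))
  if (dom[1L] >= dom[2L]) stop("fit domains do not overlap")
  sc <- space_curve(x = curve_xoy$coefficients, y = c(0, 1),
                    z = curve_yoz$coefficients, domain = dom,
                    subintervals = subintervals)
  sc$source_fits <- list(xoy = curve_xoy, yoz = curve_yoz)
  sc
}

#' Leaf-length configuration
#'
#' @param degree polynomial degree m (default 3: captures the single bend of
#'   a tomato leaflet without oscillation; configurable 1-6).
#' @param subintervals composite-Simpson subintervals (default 1000).
#' @param prealign rotate the leaf so its principal axis is the shared
#'   parameter axis before projecting (default on; makes both projections
#'   single-valued functions and the result rigid-motion invariant).
#' @return object of class `leaf_length_config`.
#' @export
leaf_length_config <- function(degree = 3L, subintervals = 1000L,
                               prealign = TRUE) {
  stopifnot(degree >= 1L, degree <= 6L, subintervals >= 10L)
  structure(list(degree = as.integer(degree),
                 subintervals = as.integer(subintervals),
                 prealign = isTRUE(prealign)),
            class = "leaf_length_config")
}

#' Leaf length by space-curve fitting
#'
#' Pipeline: optional PCA pre-alignment mapping the leaf's principal axis to
#' the shared parameter axis y; projection onto the XOY and YOZ planes;
#' least-squares polynomial fit of each projection (both parameterized by
#' y); intersection of the two extruded surfaces; arc length of the
#' resulting space curve over the observed parameter extent (no
#' extrapolation). The arc length is the leaf length.
#'
#' @param leaf a `point_cloud` or n x 3 coordinate matrix of one leaf.
#' @param cfg a [leaf_length_config()].
#' @return list: `length_mm`, `curve` (the fitted [space_curve()]),
#'   `fit_xoy`, `fit_yoz`.
#' @export
leaf_length <- function(leaf, cfg = leaf_length_config()) {
  coords <- if (inherits(leaf, "point_cloud")) leaf$coords else as.matrix(leaf)
  if (nrow(coords) < cfg$degree + 1L)
    stop("too few points for the requested polynomial degree")
  if (cfg$prealign) {
    ctr <- colMeans(coords)
    centered <- sweep(coords, 2L, ctr)
    pr <- stats::prcomp(centered, center = FALSE)
    scores <- pr$x
    # shared parameter axis y := PC1 (longest extent), x := PC2, z := PC3
    pts <- cbind(scores[, 2L], scores[, 1L], scores[, 3L])
  } else {
    pts <- coords
  }
  pxy <- project(pts, "XOY")  # (x, y)
  pyz <- project(pts, "YOZ")  # (y, z)
  fit_xoy <- fit_polynomial(pxy[, c(2L, 1L)], cfg$degree, indep = "y", dep = "x")
  fit_yoz <- fit_polynomial(pyz, cfg$degree, indep = "y", dep = "z")
  curve <- intersect_extrusions(fit_xoy, fit_yoz,
                                subintervals = cfg$subintervals)
  list(length_mm = curve$arc_length_mm, curve = curve,
       fit_xoy = fit_xoy, fit_yoz = fit_yoz)
}
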