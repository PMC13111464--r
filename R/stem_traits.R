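# Stem diameter at a fixed height above the base: slice a thin slab, align
# it with its oriented bounding box, project the slab onto the plane of
# maximum spread, and fit a circle by least squares; the diameter is 2r.

#' Stem-diameter configuration
#'
#' @param height_mm measurement height above the stem base (10 mm — i.e.
#'   1 cm above the base, the standard caliper position).
#' @param slab_half_thickness_mm half-thickness of the extracted slab
#'   (default 2.5 mm: thick enough for a well-populated ring at typical
#'   sensor density, thin enough that stem taper is negligible).
#' @param height_axis vertical axis of the cloud (default `"z"`).
#' @param projection `"auto"` picks the aligned coordinate pair whose circle
#'   fit has the smallest radius-relative residual (the projection that most
#'   resembles a ring); `"XOY"` / `"XOZ"` force a pair.
#' @param refine run Gauss-Newton refinement of the squared-residual circle
#'   objective from the algebraic start (default off; the algebraic solution
#'   already minimizes that objective).
#' @return object of class `stem_diameter_config`.
#' @export
stem_diameter_config <- function(height_mm = 10, slab_half_thickness_mm = 2.5,
                                 height_axis = c("z", "y", "x"),
                                 projection = c("auto", "XOY", "XOZ"),
                                 refine = FALSE) {
  stopifnot(slab_half_thickness_mm > 0, height_mm >= 0)
  structure(list(height_mm = height_mm,
                 slab_half_thickness_mm = slab_half_thickness_mm,
                 height_axis = match.arg(height_axis),
                 projection = match.arg(projection),
                 refine = isTRUE(refine)),
            class = "stem_diameter_config")
}

#' Extract the measurement slab from a stem cloud
#'
#' Keeps the points whose height coordinate lies within the closed interval
#' `base + h - delta, base + h + delta`, where the base is the minimum height
#' coordinate of the stem points. Order preserved.
#'
#' @param stem a stem-labeled `point_cloud` or coordinate matrix.
#' @param cfg a [stem_diameter_config()].
#' @return the slab as the same type as the input.
#' @export
slice_at_height <- function(stem, cfg = stem_diameter_config()) {
  coords <- if (inherits(stem, "point_cloud")) stem$coords else as.matrix(stem)
  ax <- match(cfg$height_axis, c("x", "y", "z"))
  h <- coords[, ax]
  base <- min(h)
  keep <- h >= base + cfg$height_mm - cfg$slab_half_thickness_mm &
    h <= base + cfg$height_mm + cfg$slab_half_thickness_mm
  if (!any(keep))
    stop("empty slab at the requested height; increase slab_half_thickness_mm")
  if (inherits(stem, "point_cloud")) stem[keep] else coords[keep, , drop = FALSE]
}

#' Oriented bounding box by principal axes
#'
#' The rotation matrix columns are the covariance eigenvectors ordered by
#' decreasing eigenvalue, each sign-fixed so its largest-magnitude entry is
#' positive, with the determinant corrected to +1; extents are the
#' half-ranges of the rotated points. A principal-axes box approximates the
#' minimum-volume box and satisfies the orthogonality condition R'R = I by
#' construction.
#'
#' @param points n x 3 coordinate matrix or `point_cloud` (>= 3
#'   non-collinear points).
#' @return object of class `oriented_bounding_box`: `rotation` (3 x 3),
#'   `center` (length 3, original frame), `half_extents` (length 3, mm).
#' @export
compute_obb <- function(points) {
  coords <- if (inherits(points, "point_cloud")) points$coords
            else as.matrix(points)
  if (nrow(coords) < 3L) stop("need at least 3 points")
  cv <- stats::cov(coords)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2L] <= max(eg$values[1L], 1e-300) * 1e-12)
    stop("degenerate point set (collinear): no oriented box")
  R <- eg$vectors  # columns ordered by decreasing eigenvalue
  for (j in 1:3) {
    i <- which.max(abs(R[, j]))
    if (R[i, j] < 0) R[, j] <- -R[, j]
  }
  if (det(R) < 0) R[, 3L] <- -R[, 3L]
  mu <- colMeans(coords)
  rot <- sweep(coords, 2L, mu) %*% R
  rng <- apply(rot, 2L, range)
  half <- (rng[2L, ] - rng[1L, ]) / 2
  mid_local <- (rng[2L, ] + rng[1L, ]) / 2
  center <- as.numeric(mu + R %*% mid_local)
  structure(list(rotation = R, center = center, half_extents = half),
            class = "oriented_bounding_box")
}

#' Rotate points into the frame of an oriented bounding box
#'
#' Centers the points on the box center and applies the rotation, so the
#' principal axis maps onto the first coordinate axis.
#'
#' @param points n x 3 matrix or `point_cloud`.
#' @param obb an [compute_obb()] result.
#' @return n x 3 matrix of aligned coordinates.
#' @export
align_with_obb <- function(points, obb) {
  coords <- if (inherits(points, "point_cloud")) points$coords
            else as.matrix(points)
  sweep(coords, 2L, obb$center) %*% obb$rotation
}

#' Least-squares circle fit
#'
#' Algebraic (Kåsa) solution: with c = r^2 - a^2 - b^2 the squared-residual
#' objective sum_k \[(x_k - a)^2 + (y_k - b)^2 - r^2\]^2 is linear least
#' squares in (a, b, c) and is minimized exactly in closed form. Optional
#' Gauss-Newton refinement of the geometric distance objective
#' sum_k (d_k - r)^2 is available. The reported residual is the RMS of
#' (distance to center - r).
#'
#' @param points2d n x 2 matrix (>= 3 non-collinear points).
#' @param refine run geometric Gauss-Newton refinement from the algebraic
#'   start.
#' @return object of class `circle_fit`: `center` (a, b), `radius`,
#'   `rms_residual`, `n`.
#' @export
fit_circle <- function(points2d, refine = FALSE) {
  P <- as.matrix(points2d)
  stopifnot(ncol(P) == 2L)
  if (nrow(P) < 3L) stop("need at least 3 points")
  x <- P[, 1L]; y <- P[, 2L]
  X <- cbind(2 * x, 2 * y, 1)
  rhs <- x^2 + y^2
  fit <- stats::lm.fit(X, rhs)
  if (fit$rank < 3L) stop("collinear points: no finite circle")
  a <- fit$coefficients[1L]; b <- fit$coefficients[2L]
  r2 <- fit$coefficients[3L] + a^2 + b^2
  if (!is.finite(r2) || r2 <= 0) stop("collinear points: no finite circle")
  r <- sqrt(r2)
  if (refine) {
    # Gauss-Newton on the geometric objective sum (d_k - r)^2
    th <- c(a, b, r)
    for (it in 1:50) {
      dx <- x - th[1L]; dy <- y - th[2L]
      d <- sqrt(dx^2 + dy^2)
      d[d == 0] <- 1e-12
      res <- d - th[3L]
      J <- cbind(-dx / d, -dy / d, -1)
      step <- tryCatch(solve(crossprod(J), crossprod(J, res)),
                       error = function(e) NULL)
      if (is.null(step)) break
      th <- th - as.numeric(step)
      if (sqrt(sum(step^2)) < 1e-12) break
    }
    a <- th[1L]; b <- th[2L]; r <- th[3L]
  }
  d <- sqrt((x - a)^2 + (y - b)^2)
  structure(list(center = c(a = unname(a), b = unname(b)), radius = unname(r),
                 rms_residual = sqrt(mean((d - r)^2)), n = nrow(P)),
            class = "circle_fit")
}

#' Stem diameter at the standard measurement height
#'
#' Pipeline: slice the slab `height_mm` above the base, compute its oriented
#' bounding box, rotate into axis alignment, project the aligned slab onto
#' the plane of maximum 2D spread (the ring's plane), fit a circle by least
#' squares; the diameter is d = 2r.
#'
#' @param stem a stem-labeled `point_cloud` or coordinate matrix.
#' @param cfg a [stem_diameter_config()].
#' @return list: `diameter_mm`, `circle` (the [fit_circle()] result), `obb`,
#'   `n_slab_points`.
#' @export
stem_diameter <- function(stem, cfg = stem_diameter_config()) {
  slab <- slice_at_height(stem, cfg)
  coords <- if (inherits(slab, "point_cloud")) slab$coords else slab
  if (nrow(coords) < 3L) stop("slab holds fewer than 3 points")
  obb <- compute_obb(coords)
  aligned <- align_with_obb(coords, obb)
  circ <- switch(cfg$projection,
    XOY = fit_circle(aligned[, c(1L, 2L), drop = FALSE], refine = cfg$refine),
    XOZ = fit_circle(aligned[, c(1L, 3L), drop = FALSE], refine = cfg$refine),
    auto = {
      # the ring plane is whichever candidate projection actually looks like
      # a ring: smallest radius-relative RMS residual. (A spread-based rule
      # fails on single-view half rings, where the slab thickness can
      # out-spread the ring's minor direction.)
      cands <- lapply(list(c(1L, 2L), c(1L, 3L)), function(ix)
        tryCatch(fit_circle(aligned[, ix, drop = FALSE],
                            refine = cfg$refine),
                 error = function(e) NULL))
      cands <- Filter(Negate(is.null), cands)
      if (length(cands) == 0L) stop("no projection admits a circle fit")
      rel <- vapply(cands, function(cf) cf$rms_residual / cf$radius,
                    numeric(1L))
      cands[[which.min(rel)]]
    })
  list(diameter_mm = 2 * circ$radius, circle = circ, obb = obb,
       n_slab_points = nrow(coords))
}
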