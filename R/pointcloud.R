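#' Colored 3D point cloud
#'
#' The universal currency of the toolkit: an n x 3 coordinate matrix in
#' millimetres, an n x 3 integer RGB matrix (channels in 0-255), and an
#' optional integer organ label per point (-1 marks unlabeled/noise points).
#'
#' @param coords numeric matrix (n x 3) of x, y, z coordinates in mm.
#' @param colors integer matrix (n x 3) of R, G, B values in \[0, 255\].
#' @param labels optional integer vector of length n; `-1` = unlabeled.
#' @return An object of class `point_cloud`.
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), ncol = 3),
#'                   matrix(sample(0:255, 30, TRUE), ncol = 3))
#' n_points(pc)
#' @export
point_cloud <- function(coords, colors, labels = NULL) {
  coords <- as.matrix(coords)
  colors <- as.matrix(colors)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  if (ncol(colors) != 3L) stop("colors must have 3 columns")
  if (nrow(coords) != nrow(colors))
    stop("coords and colors must have the same number of rows")
  if (any(!is.finite(coords))) stop("all coordinates must be finite")
  if (any(colors < 0 | colors > 255))
    stop("color channels must lie in [0, 255]")
  storage.mode(colors) <- "integer"
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(coords))
      stop("labels must have one entry per point")
  }
  colnames(coords) <- c("x", "y", "z")
  colnames(colors) <- c("red", "green", "blue")
  structure(list(coords = coords, colors = colors, labels = labels),
            class = "point_cloud")
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$coords)

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points%s\n", n_points(x),
              if (is.null(x$labels)) "" else
                sprintf(", %d label classes",
                        length(unique(x$labels[x$labels >= 0L])))))
  if (n_points(x) > 0L) {
    rng <- apply(x$coords, 2L, range)
    cat(sprintf("  extent (mm): x [%.1f, %.1f], y [%.1f, %.1f], z [%.1f, %.1f]\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

#' Subset a point cloud by index
#' @param x a `point_cloud`.
#' @param i index vector (integer or logical) over points.
#' @param ... unused.
#' @return the subset `point_cloud`, order as given by `i`.
#' @export
`[.point_cloud` <- function(x, i, ...) {
  point_cloud(x$coords[i, , drop = FALSE],
              x$colors[i, , drop = FALSE],
              if (is.null(x$labels)) NULL else x$labels[i])
}

#' Organ label scheme
#'
#' Semantic labeling convention: stem = 0, growing point (apical meristem
#' cluster) = 1, leaf instances = 2..n. [collapse_labels()] maps every leaf
#' instance id onto the single semantic class 2 ("leaf").
#'
#' @param stem_id,growing_point_id,leaf_semantic_id integer class ids.
#' @return An object of class `label_scheme`.
#' @export
label_scheme <- function(stem_id = 0L, growing_point_id = 1L,
                         leaf_semantic_id = 2L) {
  ids <- c(stem_id, growing_point_id, leaf_semantic_id)
  if (anyDuplicated(ids)) stop("label ids must be disjoint")
  structure(list(stem_id = as.integer(stem_id),
                 growing_point_id = as.integer(growing_point_id),
                 leaf_semantic_id = as.integer(leaf_semantic_id)),
            class = "label_scheme")
}

#' Collapse leaf-instance labels to the semantic class set
#'
#' Leaf instances carry ids 2..n; semantic evaluation and network training use
#' three classes {0 = stem, 1 = growing point, 2 = leaf}. Point order is
#' preserved.
#'
#' @param cloud a labeled `point_cloud`.
#' @param scheme a [label_scheme()].
#' @return the cloud with labels mapped into {0, 1, 2}.
#' @export
collapse_labels <- function(cloud, scheme = label_scheme()) {
  if (is.null(cloud$labels)) stop("collapse_labels requires a labeled cloud")
  lab <- cloud$labels
  if (all(lab < 0L)) stop("cloud has no usable labels (all unlabeled)")
  if (any(lab < 0L))
    stop("negative labels present; remove unlabeled/noise points first")
  out <- lab
  out[lab >= 2L] <- scheme$leaf_semantic_id
  out[lab == 0L] <- scheme$stem_id
  out[lab == 1L] <- scheme$growing_point_id
  cloud$labels <- out
  cloud
}

#' Region-of-interest configuration
#'
#' Per-axis closed intervals in mm; `NULL` leaves an axis unbounded. In the
#' camera frame of a downward-facing depth sensor the typical defaults are a
#' working-distance window on the depth axis and a height window on the
#' vertical axis, e.g. `roi_config(y = c(500, 650), z = c(350, 450))`.
#'
#' @param x,y,z length-2 numeric `c(lo, hi)` or `NULL` (unbounded).
#' @return An object of class `roi_config`.
#' @export
roi_config <- function(x = NULL, y = NULL, z = NULL) {
  chk <- function(v, nm) {
    if (is.null(v)) return(NULL)
    if (length(v) != 2L || any(!is.finite(v)) || v[1] > v[2])
      stop(sprintf("interval for %s must be c(lo, hi) with lo <= hi", nm))
    as.numeric(v)
  }
  structure(list(x = chk(x, "x"), y = chk(y, "y"), z = chk(z, "z")),
            class = "roi_config")
}

#' Condition filtering by coordinate ranges
#'
#' Retains exactly the points whose coordinates fall inside every bounded
#' interval (closed bounds: a point exactly on a bound is kept). Point order,
#' colors and labels are preserved. Idempotent.
#'
#' @param cloud a `point_cloud`.
#' @param cfg a [roi_config()].
#' @return the filtered `point_cloud` (possibly empty).
#' @export
roi_filter <- function(cloud, cfg) {
  stopifnot(inherits(cfg, "roi_config"))
  keep <- rep(TRUE, n_points(cloud))
  for (ax in 1:3) {
    iv <- cfg[[ax]]
    if (!is.null(iv))
      keep <- keep & cloud$coords[, ax] >= iv[1] & cloud$coords[, ax] <= iv[2]
  }
  cloud[keep]
}

#' Augmentation scheme
#'
#' Rigid-variant expansion of each sample: rotations about the vertical axis
#' through the cloud centroid, optionally composed with a horizontal mirror.
#' The default (8 rotations at 45 degree steps x {identity, mirror}) emits
#' exactly 16 variants per input cloud, matching a 97-plant corpus expanding
#' to 1,552 samples under a 68/29 split.
#'
#' @param angles_deg ordered numeric rotation angles in degrees.
#' @param mirror logical; compose every rotation with a horizontal mirror.
#' @param axis rotation axis, one of `"x"`, `"y"`, `"z"` (vertical default).
#' @return An object of class `augmentation_scheme`.
#' @export
augmentation_scheme <- function(angles_deg = seq(0, 315, by = 45),
                                mirror = TRUE, axis = "z") {
  if (length(angles_deg) == 0L) stop("angle list must be non-empty")
  axis <- match.arg(axis, c("x", "y", "z"))
  structure(list(angles_deg = as.numeric(angles_deg),
                 mirror = isTRUE(mirror), axis = axis),
            class = "augmentation_scheme")
}

rotation_about_axis <- function(angle_deg, axis) {
  th <- angle_deg * pi / 180
  c2 <- cos(th); s2 <- sin(th)
  R2 <- matrix(c(c2, -s2, s2, c2), 2L, 2L, byrow = TRUE)
  R <- diag(3)
  idx <- switch(axis, x = c(2L, 3L), y = c(3L, 1L), z = c(1L, 2L))
  R[idx, idx] <- R2
  R
}

#' Expand a cloud into its rigid augmentation variants
#'
#' Applies each rotation of the scheme about its axis through the cloud
#' centroid; with `mirror` on, each rotated variant is additionally emitted
#' with the first in-plane coordinate reflected (a horizontal mirror in the
#' centroid frame). The 0-degree unmirrored variant is the input itself.
#'
#' @param cloud a `point_cloud`.
#' @param scheme an [augmentation_scheme()].
#' @return list of `point_cloud` of length `length(angles) * (1 + mirror)`.
#' @export
augment <- function(cloud, scheme = augmentation_scheme()) {
  stopifnot(inherits(scheme, "augmentation_scheme"))
  ctr <- colMeans(cloud$coords)
  centered <- sweep(cloud$coords, 2L, ctr)
  mirror_axis <- switch(scheme$axis, x = 2L, y = 3L, z = 1L)
  out <- vector("list", length(scheme$angles_deg) * (1L + scheme$mirror))
  j <- 0L
  for (ang in scheme$angles_deg) {
    R <- rotation_about_axis(ang, scheme$axis)
    rot <- if (ang == 0) cloud$coords else
      sweep(centered %*% t(R), 2L, ctr, `+`)
    j <- j + 1L
    v <- cloud
    v$coords <- rot
    out[[j]] <- v
    if (scheme$mirror) {
      m <- sweep(rot, 2L, ctr)
      m[, mirror_axis] <- -m[, mirror_axis]
      j <- j + 1L
      vm <- cloud
      vm$coords <- sweep(m, 2L, ctr, `+`)
      out[[j]] <- vm
    }
  }
  out
}

#' Coordinate inversion
#'
#' Negates every coordinate, (x, y, z) -> (-x, -y, -z); colors and labels are
#' unchanged. Available as an opt-in augmentation operator, separate from the
#' default rotation x mirror scheme.
#'
#' @param cloud a `point_cloud`.
#' @return the inverted `point_cloud`.
#' @export
coordinate_inversion <- function(cloud) {
  cloud$coords <- -cloud$coords
  cloud
}

#' Plant-level train/test split
#'
#' Splits `n` plant ids at the given ratio with nearest-integer rounding of
#' the training fraction, before any augmentation (augmenting each split
#' independently prevents leakage of rigid variants across the split). With
#' `n = 97` and the default 7:3 ratio this yields 68 training and 29 testing
#' plants.
#'
#' @param n number of plants.
#' @param train_frac training fraction (default 0.7).
#' @param seed integer seed for the shuffle; `NULL` keeps 1..n order.
#' @return list with integer id vectors `train` and `test`.
#' @export
split_plants <- function(n, train_frac = 0.7, seed = NULL) {
  stopifnot(n >= 1L, train_frac > 0, train_frac < 1)
  ids <- seq_len(n)
  if (!is.null(seed)) {
    ids <- local_rng(seed, sample(ids))
  }
  k <- round(train_frac * n)
  list(train = sort(ids[seq_len(k)]), test = sort(ids[-seq_len(k)]))
}
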