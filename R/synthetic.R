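#' Synthetic tomato plant specification
#'
#' Parameters of the deterministic generator that emulates single-view depth
#' acquisitions of greenhouse tomato seedlings at the three-to-seven-true-leaf
#' stage: a vertical stem cylinder of known diameter, curved leaf bands whose
#' midrib arc lengths are known in closed form, a dense growing-point cluster
#' at the stem apex, organ color palettes, and gray flying-pixel noise.
#' Every random draw is governed by `seed`, so a spec fixes its plant
#' bit-exactly.
#'
#' @param stem_diameter_mm stem cylinder diameter (measured range of real
#'   seedlings spans roughly 4-13 mm).
#' @param stem_height_mm stem height.
#' @param leaf_count number of leaves (3-7 at the emulated stage).
#' @param leaf_length_mm per-leaf midrib chord length(s), recycled.
#' @param leaf_arch_mm per-leaf vertical arch amplitude(s), recycled; the
#'   midrib is `(0, L t, A sin(pi t))` in the leaf frame, t in \[0, 1\].
#' @param leaf_half_width_mm half-width of the leaf band around the midrib.
#' @param growing_point_radius_mm radius of the apical cluster.
#' @param points_per_mm2 surface sampling density.
#' @param noise_sigma_mm isotropic Gaussian jitter applied to every surface
#'   point (sensor noise).
#' @param flying_pixel_count gray noise points appended near silhouettes.
#' @param palettes named list of `list(mean = RGB, sd = scalar)` for
#'   `leaf`, `stem`, `growing_point`, `noise`.
#' @param view_direction `NULL` for full-surround sampling, or a length-3
#'   camera viewing direction: stem-surface points whose outward normal faces
#'   away from the camera are culled (single-view emulation).
#' @param seed integer seed.
#' @return an object of class `plant_spec`.
#' @export
plant_spec <- function(stem_diameter_mm = 8,
                       stem_height_mm = 150,
                       leaf_count = 5,
                       leaf_length_mm = 100,
                       leaf_arch_mm = 40,
                       leaf_half_width_mm = 8,
                       growing_point_radius_mm = 12,
                       points_per_mm2 = 0.35,
                       noise_sigma_mm = 0.1,
                       flying_pixel_count = 0,
                       palettes = default_palettes(),
                       view_direction = NULL,
                       seed = 1L) {
  stopifnot(stem_diameter_mm > 0, stem_height_mm > 0, leaf_count >= 0,
            all(leaf_length_mm > 0), leaf_half_width_mm > 0,
            growing_point_radius_mm > 0, points_per_mm2 > 0,
            noise_sigma_mm >= 0, flying_pixel_count >= 0)
  for (p in palettes)
    if (any(p$mean < 0 | p$mean > 255)) stop("palette means must be in [0,255]")
  structure(list(stem_diameter_mm = stem_diameter_mm,
                 stem_height_mm = stem_height_mm,
                 leaf_count = as.integer(leaf_count),
                 leaf_length_mm = rep_len(leaf_length_mm, max(1, leaf_count)),
                 leaf_arch_mm = rep_len(leaf_arch_mm, max(1, leaf_count)),
                 leaf_half_width_mm = leaf_half_width_mm,
                 growing_point_radius_mm = growing_point_radius_mm,
                 points_per_mm2 = points_per_mm2,
                 noise_sigma_mm = noise_sigma_mm,
                 flying_pixel_count = as.integer(flying_pixel_count),
                 palettes = palettes,
                 view_direction = view_direction,
                 seed = as.integer(seed)),
            class = "plant_spec")
}

#' Default organ color palettes
#'
#' Plant-green leaves, green-brown stems, a brighter apical cluster and
#' neutral-gray flying pixels. Under these palettes mean leaf ExG is about
#' 180 and mean noise ExG about 0, the color separation that K-means and
#' ExG-threshold denoising exploit.
#' @return named list of `list(mean, sd)` palettes.
#' @export
default_palettes <- function() {
  list(leaf          = list(mean = c(60, 150, 60),  sd = 12),
       stem          = list(mean = c(90, 130, 60),  sd = 10),
       growing_point = list(mean = c(95, 170, 80),  sd = 10),
       noise         = list(mean = c(130, 130, 130), sd = 8))
}

.draw_colors <- function(n, palette) {
  m <- matrix(rnorm(3L * n, mean = rep(palette$mean, each = n),
                    sd = palette$sd), ncol = 3L)
  matrix(as.integer(pmin(255, pmax(0, round(m)))), ncol = 3L)
}

# Arc length of the canonical midrib (0, L t, A sin(pi t)) over [0, 1] by
# composite Simpson quadrature on the analytic speed.
.midrib_arc_length <- function(L, A, n = 1e5) {
  speed <- function(t) sqrt(L^2 + (A * pi * cos(pi * t))^2)
  simpson_quadrature(speed, 0, 1, n)
}

#' Generate a labeled synthetic plant with ground truth
#'
#' Builds stem (label 0: cylinder-surface samples), growing point (label 1:
#' dense ellipsoidal cluster at the apex), and leaves (labels 2..n: band
#' samples around arched midribs attached along the stem), draws colors from
#' the organ palettes, optionally appends flying pixels, and records the
#' ground truth every trait module is tested against: exact stem diameter and
#' per-leaf midrib arc lengths computed by fine quadrature on the generating
#' curves.
#'
#' @param spec a [plant_spec()].
#' @return list with elements `cloud` (a labeled [point_cloud()]) and
#'   `truth` (list: `stem_diameter_mm`, `leaf_lengths_mm`, `leaf_labels`).
#' @export
generate_plant <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  local_rng(spec$seed, {
    r <- spec$stem_diameter_mm / 2
    h <- spec$stem_height_mm
    dens <- spec$points_per_mm2
    sig <- spec$noise_sigma_mm

    # stem: lateral cylinder surface
    n_stem <- max(30L, round(dens * pi * spec$stem_diameter_mm * h))
    theta <- runif(n_stem, 0, 2 * pi)
    if (!is.null(spec$view_direction)) {
      v <- spec$view_direction / sqrt(sum(spec$view_direction^2))
      keep <- cos(theta) * v[1] + sin(theta) * v[2] < 0  # normal faces camera
      theta <- theta[keep]
      n_stem <- length(theta)
    }
    zs <- runif(n_stem, 0, h)
    stem <- cbind(r * cos(theta), r * sin(theta), zs) +
      matrix(rnorm(3L * n_stem, sd = sig), ncol = 3L)

    # growing point: dense ellipsoidal cluster at the apex
    gr <- spec$growing_point_radius_mm
    n_gp <- max(30L, round(2 * dens * 4 * pi * gr^2))
    gp <- cbind(rnorm(n_gp, sd = gr / 2), rnorm(n_gp, sd = gr / 2),
                h + rnorm(n_gp, sd = gr / 3))

    # leaves: bands around arched midribs, spiral phyllotaxis
    leaves <- list()
    leaf_lengths <- numeric(0)
    if (spec$leaf_count > 0L) {
      attach_frac <- seq(0.35, 0.95, length.out = spec$leaf_count)
      azimuth <- (seq_len(spec$leaf_count) - 1L) * 137.5 * pi / 180 +
        runif(1, 0, 2 * pi)
      for (i in seq_len(spec$leaf_count)) {
        L <- spec$leaf_length_mm[i]; A <- spec$leaf_arch_mm[i]
        w <- spec$leaf_half_width_mm
        n_leaf <- max(50L, round(dens * L * 2 * w))
        t <- runif(n_leaf); s <- runif(n_leaf, -w, w)
        a <- azimuth[i]
        dir <- c(cos(a), sin(a), 0); lat <- c(-sin(a), cos(a), 0)
        base <- c(r * cos(a), r * sin(a), attach_frac[i] * h)
        pts <- cbind(base[1] + dir[1] * L * t + lat[1] * s,
                     base[2] + dir[2] * L * t + lat[2] * s,
                     base[3] + A * sin(pi * t)) +
          matrix(rnorm(3L * n_leaf, sd = sig), ncol = 3L)
        leaves[[i]] <- pts
        leaf_lengths[i] <- .midrib_arc_length(L, A)
      }
    }

    coords <- do.call(rbind, c(list(stem, gp), leaves))
    labels <- c(rep(0L, n_stem), rep(1L, n_gp),
                unlist(lapply(seq_along(leaves),
                              function(i) rep(i + 1L, nrow(leaves[[i]])))))
    pal <- spec$palettes
    colors <- rbind(.draw_colors(n_stem, pal$stem),
                    .draw_colors(n_gp, pal$growing_point),
                    .draw_colors(length(labels) - n_stem - n_gp, pal$leaf))
    cloud <- point_cloud(coords, colors, labels)
    if (spec$flying_pixel_count > 0L)
      cloud <- add_flying_pixels(cloud, spec$flying_pixel_count,
                                 palette = pal$noise,
                                 seed = derive_seed(spec$seed, 9999L))
    list(cloud = cloud,
         truth = list(stem_diameter_mm = spec$stem_diameter_mm,
                      leaf_lengths_mm = leaf_lengths,
                      leaf_labels = if (spec$leaf_count > 0L)
                        seq_len(spec$leaf_count) + 1L else integer(0)))
  })
}

#' Append flying-pixel noise to a cloud
#'
#' Emulates the mixed-return edge artifacts of time-of-flight sensors: gray
#' points offset outward from randomly chosen silhouette points along seeded
#' random directions (5-30 mm), labeled -1.
#'
#' @param cloud a `point_cloud`.
#' @param n number of noise points to append.
#' @param offset_range length-2 offset magnitude range in mm.
#' @param palette noise color palette, `list(mean, sd)`.
#' @param seed integer seed.
#' @return the cloud with exactly `n` points appended (label -1).
#' @export
add_flying_pixels <- function(cloud, n, offset_range = c(5, 30),
                              palette = default_palettes()$noise,
                              seed = 1L) {
  n <- as.integer(n)
  if (n == 0L) return(cloud)
  local_rng(seed, {
    base_idx <- sample.int(n_points(cloud), n, replace = TRUE)
    dir <- matrix(rnorm(3L * n), ncol = 3L)
    dir <- dir / sqrt(rowSums(dir^2))
    mag <- runif(n, offset_range[1], offset_range[2])
    pts <- cloud$coords[base_idx, , drop = FALSE] + dir * mag
    cols <- .draw_colors(n, palette)
    labs <- if (is.null(cloud$labels)) NULL else c(cloud$labels, rep(-1L, n))
    point_cloud(rbind(cloud$coords, pts), rbind(cloud$colors, cols), labs)
  })
}

#' Generate a corpus of synthetic plants
#'
#' Draws per-plant specs from the given ranges under per-plant seeds derived
#' from the master seed, so the whole corpus is reproducible from one integer.
#'
#' @param n number of plants.
#' @param stem_diameter_range,leaf_count_range,leaf_length_range,stem_height_range
#'   sampling ranges for the per-plant draws.
#' @param points_per_mm2,noise_sigma_mm,flying_pixel_count passed through to
#'   every [plant_spec()].
#' @param seed master integer seed.
#' @return list of `n` plants as returned by [generate_plant()].
#' @export
generate_dataset <- function(n,
                             stem_diameter_range = c(4, 13),
                             leaf_count_range = c(3L, 7L),
                             leaf_length_range = c(70, 130),
                             stem_height_range = c(120, 180),
                             points_per_mm2 = 0.35,
                             noise_sigma_mm = 0.1,
                             flying_pixel_count = 0L,
                             seed = 1L) {
  stopifnot(n >= 1L)
  lapply(seq_len(n), function(i) {
    si <- derive_seed(seed, i)
    pars <- local_rng(si, list(
      d = runif(1, stem_diameter_range[1], stem_diameter_range[2]),
      lc = sample(seq(leaf_count_range[1], leaf_count_range[2]), 1L),
      ll = runif(1, leaf_length_range[1], leaf_length_range[2]),
      hh = runif(1, stem_height_range[1], stem_height_range[2])))
    generate_plant(plant_spec(
      stem_diameter_mm = pars$d, stem_height_mm = pars$hh,
      leaf_count = pars$lc, leaf_length_mm = pars$ll,
      leaf_arch_mm = 0.4 * pars$ll,
      points_per_mm2 = points_per_mm2, noise_sigma_mm = noise_sigma_mm,
      flying_pixel_count = flying_pixel_count,
      seed = derive_seed(si, 1L)))
  })
}
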