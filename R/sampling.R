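#' Voxel-grid configuration
#'
#' @param voxel_size_mm cube edge length s in mm (> 0). Cells are half-open
#'   `[lo, lo + s)` anchored at the cloud's minimum corner; the global
#'   maximum corner is clamped into the last cell.
#' @param representative one of `"centroid"` (mean of coords and colors; the
#'   noise-suppressing default), `"voxel_center"`, or `"nearest_to_centroid"`
#'   (an original point index).
#' @return object of class `voxel_config`.
#' @export
voxel_config <- function(voxel_size_mm,
                         representative = c("centroid", "voxel_center",
                                            "nearest_to_centroid")) {
  if (voxel_size_mm <= 0) stop("voxel size must be > 0")
  structure(list(voxel_size_mm = voxel_size_mm,
                 representative = match.arg(representative)),
            class = "voxel_config")
}

#' Farthest-point-sampling configuration
#'
#' @param m target sample count.
#' @param start `"index0"` (deterministic default) or `"random"` (seeded).
#' @param seed seed for the random start rule.
#' @return object of class `fps_config`.
#' @export
fps_config <- function(m, start = c("index0", "random"), seed = 1L) {
  stopifnot(m >= 1)
  structure(list(m = as.integer(m), start = match.arg(start),
                 seed = as.integer(seed)),
            class = "fps_config")
}

new_sampling_result <- function(cloud, indices, distance_ops, elapsed_s,
                                method, config) {
  structure(list(cloud = cloud, indices = indices,
                 count = n_points(cloud),
                 distance_ops = as.numeric(distance_ops),
                 elapsed_s = elapsed_s, method = method, config = config),
            class = "sampling_result")
}

#' @export
print.sampling_result <- function(x, ...) {
  cat(sprintf("<sampling_result> %s: %d points, %.0f distance ops, %.4f s\n",
              x$method, x$count, x$distance_ops, x$elapsed_s))
  invisible(x)
}

#' Voxel-grid downsampling (VGDS)
#'
#' Partitions space into cubes of edge `s` anchored at the cloud's minimum
#' corner and replaces the points of each occupied voxel by one
#' representative. Output is ordered by lexicographic voxel index. The
#' centroid and voxel-center modes evaluate no point-to-point distances
#' (`distance_ops = 0`); nearest-to-centroid counts one distance per voxel
#' member.
#'
#' @param cloud a non-empty `point_cloud`.
#' @param cfg a [voxel_config()].
#' @return a `sampling_result`; `indices` is non-`NULL` only for the
#'   nearest-to-centroid mode.
#' @export
voxel_downsample <- function(cloud, cfg) {
  stopifnot(inherits(cfg, "voxel_config"), n_points(cloud) >= 1L)
  t0 <- proc.time()[["elapsed"]]
  s <- cfg$voxel_size_mm
  minc <- apply(cloud$coords, 2L, min)
  maxc <- apply(cloud$coords, 2L, max)
  # half-open cells [lo, lo + s); the clamp only guards the global max
  # corner against floating-point wobble, so exact-corner points stay in
  # the top cell rather than opening a spurious one
  nmax <- pmax(floor((maxc - minc) / s + 1e-12), 0)
  vi <- floor(sweep(sweep(cloud$coords, 2L, minc), 2L, s, `/`))
  vi <- pmin(vi, matrix(nmax, nrow(vi), 3L, byrow = TRUE))
  dt <- data.table::data.table(
    vx = vi[, 1L], vy = vi[, 2L], vz = vi[, 3L],
    x = cloud$coords[, 1L], y = cloud$coords[, 2L], z = cloud$coords[, 3L],
    r = as.numeric(cloud$colors[, 1L]), g = as.numeric(cloud$colors[, 2L]),
    b = as.numeric(cloud$colors[, 3L]),
    lab = if (is.null(cloud$labels)) NA_integer_ else cloud$labels,
    idx = seq_len(n_points(cloud)))
  vx <- vy <- vz <- x <- y <- z <- r <- g <- b <- lab <- idx <- NULL # R CMD check
  majority <- function(l) {
    ul <- unique(l)
    if (length(ul) == 1L) return(ul[1L])
    ul[which.max(tabulate(match(l, ul)))]
  }
  dops <- 0
  if (cfg$representative == "centroid") {
    agg <- dt[, list(x = mean(x), y = mean(y), z = mean(z),
                     r = mean(r), g = mean(g), b = mean(b),
                     lab = majority(lab)),
              keyby = list(vx, vy, vz)]
    indices <- NULL
  } else if (cfg$representative == "voxel_center") {
    agg <- dt[, list(x = (vx[1L] + 0.5) * s + minc[1L],
                     y = (vy[1L] + 0.5) * s + minc[2L],
                     z = (vz[1L] + 0.5) * s + minc[3L],
                     r = mean(r), g = mean(g), b = mean(b),
                     lab = majority(lab)),
              keyby = list(vx, vy, vz)]
    indices <- NULL
  } else {
    agg <- dt[, {
      cx <- mean(x); cy <- mean(y); cz <- mean(z)
      d2 <- (x - cx)^2 + (y - cy)^2 + (z - cz)^2
      i <- which.min(d2)
      list(x = x[i], y = y[i], z = z[i], r = r[i], g = g[i], b = b[i],
           lab = lab[i], pick = idx[i], nv = length(d2))
    }, keyby = list(vx, vy, vz)]
    dops <- sum(agg$nv)
    indices <- agg$pick
  }
  labs <- if (is.null(cloud$labels)) NULL else as.integer(agg$lab)
  out <- point_cloud(cbind(agg$x, agg$y, agg$z),
                     pmax(pmin(round(cbind(agg$r, agg$g, agg$b)), 255), 0),
                     labs)
  new_sampling_result(out, indices, dops,
                      proc.time()[["elapsed"]] - t0, "vgds", cfg)
}

#' Farthest point sampling (FPS)
#'
#' Iterative greedy max-min selection: each next index maximizes the minimum
#' squared Euclidean distance to the already-selected set (ties broken by
#' lowest index). The `distance_ops` counter increases by N per iteration —
#' the (m-1)N cost that makes FPS expensive on large clouds, independent of
#' hardware.
#'
#' @param cloud a `point_cloud`.
#' @param cfg an [fps_config()].
#' @return a `sampling_result` with `indices` into the input cloud.
#' @export
farthest_point_sample <- function(cloud, cfg) {
  stopifnot(inherits(cfg, "fps_config"))
  n <- n_points(cloud)
  if (cfg$m > n) stop("target count m exceeds the point count")
  start <- if (cfg$start == "index0") 1L else
    local_rng(cfg$seed, sample.int(n, 1L))
  t0 <- proc.time()[["elapsed"]]
  res <- .fps_cpp(cloud$coords, cfg$m, start - 1L)
  el <- proc.time()[["elapsed"]] - t0
  new_sampling_result(cloud[res$indices], res$indices, res$distance_ops,
                      el, "fps", cfg)
}

#' Match a voxel size to an exact output count
#'
#' The voxel size controls sampling density only indirectly; this routine
#' bisects the voxel size over (0, cloud diameter\] for at most 50 iterations
#' until the occupied-voxel count is within `tolerance` of the target, then
#' forces the count to exactly `m`: surplus representatives are dropped by a
#' seeded uniform draw, a deficit is padded by duplicating seeded random
#' representatives.
#'
#' @param cloud a `point_cloud`.
#' @param m target count (1 <= m <= N).
#' @param tolerance acceptable |count - m| before the exact drop/pad step.
#' @param seed integer seed for the drop/pad draws.
#' @param representative passed to [voxel_config()].
#' @return list with `config` (the matched [voxel_config()]) and `result`
#'   (a `sampling_result` with exactly `m` points).
#' @export
match_voxel_size_to_count <- function(cloud, m, tolerance = 0L, seed = 1L,
                                      representative = "centroid") {
  n <- n_points(cloud)
  stopifnot(m >= 1, m <= n)
  diam <- cloud_diameter(cloud$coords)
  if (diam == 0) {
    if (m > 1L) stop("degenerate cloud (all points identical) with m > 1")
    cfg <- voxel_config(1, representative)
    return(list(config = cfg, result = voxel_downsample(cloud, cfg)))
  }
  lo <- diam * 1e-7  # fine grid: one point per voxel for separated points
  hi <- diam
  minc <- apply(cloud$coords, 2L, min)
  maxc <- apply(cloud$coords, 2L, max)
  count_at <- function(s) {
    # occupied-voxel count only: cheap enough to run every bisection step
    nmax <- pmax(floor((maxc - minc) / s + 1e-12), 0)
    vi <- floor(sweep(sweep(cloud$coords, 2L, minc), 2L, s, `/`))
    vi <- pmin(vi, matrix(nmax, nrow(vi), 3L, byrow = TRUE))
    nrow(unique(data.table::as.data.table(vi)))
  }
  best_cnt <- -Inf; best_s <- NA_real_
  for (it in seq_len(50L)) {
    s <- sqrt(lo * hi)  # geometric bisection: s spans orders of magnitude
    cnt <- count_at(s)
    if (abs(cnt - m) < abs(best_cnt - m)) {
      best_cnt <- cnt; best_s <- s
    }
    if (abs(cnt - m) <= tolerance) break
    if (cnt > m) lo <- s else hi <- s
  }
  res <- voxel_downsample(cloud, voxel_config(best_s, representative))
  cl <- res$cloud
  if (res$count > m) {
    keep <- sort(local_rng(seed, sample.int(res$count, m)))
    cl <- cl[keep]
    if (!is.null(res$indices)) res$indices <- res$indices[keep]
  } else if (res$count < m) {
    pad <- local_rng(seed, sample.int(res$count, m - res$count, replace = TRUE))
    sel <- c(seq_len(res$count), pad)
    cl <- cl[sel]
    if (!is.null(res$indices)) res$indices <- res$indices[sel]
  }
  res$cloud <- cl
  res$count <- m
  list(config = voxel_config(best_s, representative), result = res)
}

#' Benchmark sampling strategies at matched output counts
#'
#' Runs each method on each cloud with both forced to identical output
#' counts (`m`), recording output count, the hardware-independent
#' distance-operation counter, and wall-clock time, plus mean and standard
#' deviation across clouds per method.
#'
#' @param clouds list of `point_cloud`s (at least one).
#' @param m matched output count.
#' @param methods subset of `c("vgds", "fps")`.
#' @param seed seed for the VGDS exact-count matching.
#' @return `data.frame` with one row per cloud x method (columns `method`,
#'   `grid_size_mm`, `input_points`, `output_points`, `runtime_s`,
#'   `distance_ops`); per-method mean/sd summary in attribute `"summary"`.
#' @export
benchmark_sampling <- function(clouds, m, methods = c("vgds", "fps"),
                               seed = 1L) {
  stopifnot(length(clouds) >= 1L)
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (ci in seq_along(clouds)) {
    cl <- clouds[[ci]]
    for (mth in methods) {
      if (mth == "vgds") {
        # calibrate the grid size to the matched count, then time the voxel
        # pass itself (the benchmark quantity; calibration is setup)
        mr <- match_voxel_size_to_count(cl, m, seed = derive_seed(seed, ci))
        rows[[length(rows) + 1L]] <- data.frame(
          cloud = ci, method = "vgds",
          grid_size_mm = mr$config$voxel_size_mm,
          input_points = n_points(cl), output_points = mr$result$count,
          runtime_s = mr$result$elapsed_s,
          distance_ops = mr$result$distance_ops)
      } else {
        fr <- farthest_point_sample(cl, fps_config(m))
        rows[[length(rows) + 1L]] <- data.frame(
          cloud = ci, method = "fps", grid_size_mm = NA_real_,
          input_points = n_points(cl), output_points = fr$count,
          runtime_s = fr$elapsed_s, distance_ops = fr$distance_ops)
      }
    }
  }
  out <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(out, out$method), function(d)
    data.frame(method = d$method[1L],
               mean_runtime_s = mean(d$runtime_s),
               sd_runtime_s = stats::sd(d$runtime_s),
               mean_distance_ops = mean(d$distance_ops),
               sd_distance_ops = stats::sd(d$distance_ops))))
  summ$sd_runtime_s[is.na(summ$sd_runtime_s)] <- 0
  summ$sd_distance_ops[is.na(summ$sd_distance_ops)] <- 0
  attr(out, "summary") <- summ
  out
}
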