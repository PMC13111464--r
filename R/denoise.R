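#' Excess Green Index
#'
#' ExG = 2G - R - B per point: large for green vegetation, near zero for
#' neutral gray surfaces such as flying pixels. Range \[-510, 510\] for 8-bit
#' channels.
#'
#' @param colors n x 3 integer RGB matrix (channels in 0-255), or a
#'   `point_cloud`.
#' @return integer vector of per-point ExG values.
#' @export
exg <- function(colors) {
  if (inherits(colors, "point_cloud")) colors <- colors$colors
  colors <- as.matrix(colors)
  if (any(colors < 0 | colors > 255))
    stop("color channels must lie in [0, 255]")
  as.integer(2L * colors[, 2L] - colors[, 1L] - colors[, 3L])
}

#' ExG configuration
#'
#' @param threshold `"auto"` for histogram-valley selection, or a fixed
#'   numeric threshold in \[-510, 510\] (values outside are allowed only to
#'   express degenerate keep-all / drop-all filters).
#' @param bin_width histogram bin width in ExG units (default 10: 103 bins
#'   over the full range, smooth enough for valley detection).
#' @return object of class `exg_config`.
#' @export
exg_config <- function(threshold = "auto", bin_width = 10) {
  if (is.numeric(threshold) && length(threshold) != 1L)
    stop("fixed threshold must be a single number")
  stopifnot(bin_width > 0)
  structure(list(threshold = threshold, bin_width = bin_width),
            class = "exg_config")
}

#' Automatic ExG valley threshold
#'
#' Histograms the ExG values, locates the two highest-count modes (local
#' maxima of the binned counts), and returns the center of the lowest-count
#' bin strictly between them — the valley separating the vegetation and
#' non-vegetation peaks. Unimodal input falls back to the midpoint between
#' the mean and the maximum.
#'
#' @param values numeric ExG values (at least 2 distinct).
#' @param cfg an [exg_config()].
#' @return the threshold value.
#' @export
exg_auto_threshold <- function(values, cfg = exg_config()) {
  if (length(unique(values)) < 2L)
    stop("constant ExG input: no vegetation/background separation possible")
  bw <- cfg$bin_width
  lo <- floor(min(values) / bw) * bw
  hi <- ceiling((max(values) + 1e-9) / bw) * bw
  breaks <- seq(lo, hi + bw, by = bw)
  counts <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  centers <- breaks[-length(breaks)] + bw / 2
  nb <- length(counts)
  # local maxima of the binned counts (plateau-tolerant at the edges)
  is_peak <- vapply(seq_len(nb), function(i) {
    l <- if (i > 1L) counts[i - 1L] else -1
    r <- if (i < nb) counts[i + 1L] else -1
    counts[i] > 0 && counts[i] >= l && counts[i] >= r && (counts[i] > l || counts[i] > r)
  }, logical(1L))
  peaks <- which(is_peak)
  # a mode must carry real mass; stray tail bins are not vegetation peaks
  peaks <- peaks[counts[peaks] >= 0.05 * max(counts)]
  if (length(peaks) < 2L)
    return((mean(values) + max(values)) / 2)
  top2 <- peaks[order(counts[peaks], decreasing = TRUE)][1:2]
  a <- min(top2); b <- max(top2)
  if (b - a < 2L)  # adjacent modes: no interior bin, split between them
    return((centers[a] + centers[b]) / 2)
  mid <- (a + 1L):(b - 1L)
  centers[mid[which.min(counts[mid])]]
}

#' Segment vegetation by ExG threshold
#'
#' Retains exactly the points with ExG at or above the threshold (fixed, or
#' chosen per sample by [exg_auto_threshold()]); point order is preserved.
#'
#' @param cloud a colored `point_cloud`.
#' @param cfg an [exg_config()].
#' @return the retained `point_cloud`.
#' @export
exg_segment <- function(cloud, cfg = exg_config()) {
  v <- exg(cloud)
  thr <- if (identical(cfg$threshold, "auto"))
    exg_auto_threshold(v, cfg) else cfg$threshold
  cloud[v >= thr]
}

#' Choose the number of color clusters
#'
#' Counts the dominant modes of the color distribution — peaks of smoothed
#' luminance and hue densities exceeding a prominence fraction of the tallest
#' peak — and clamps the answer to \[2, 4\], returning 2 when the evidence is
#' ambiguous. Mirrors the practice of setting k from the number of major
#' peaks in the RGB color histogram.
#'
#' @param colors n x 3 RGB matrix or a `point_cloud`.
#' @param prominence minimum peak height as a fraction of the tallest peak.
#' @return integer k in \[2, 4\].
#' @export
choose_k <- function(colors, prominence = 0.25) {
  if (inherits(colors, "point_cloud")) colors <- colors$colors
  colors <- as.matrix(colors)
  if (nrow(colors) == 0L) stop("empty color set")
  count_modes <- function(x, bw) {
    if (length(unique(x)) < 2L) return(1L)
    d <- stats::density(x, bw = bw, n = 256L)
    y <- d$y
    pk <- which(diff(sign(diff(y))) == -2) + 1L
    if (y[1] > y[2]) pk <- c(1L, pk)
    if (y[256] > y[255]) pk <- c(pk, 256L)
    sum(y[pk] >= prominence * max(y))
  }
  lum <- 0.299 * colors[, 1] + 0.587 * colors[, 2] + 0.114 * colors[, 3]
  hsv <- grDevices::rgb2hsv(t(colors))
  # hue is only meaningful for saturated points; near-neutral palettes get
  # no say, otherwise gray noise scatters over all hues
  hue <- hsv[1L, ] * 360
  sat <- hsv[2L, ]
  saturated <- sat > 0.15
  hue_modes <- if (mean(saturated) < 0.25) 1L else
    count_modes(hue[saturated], bw = 12)
  k <- max(count_modes(lum, bw = 8), hue_modes)
  as.integer(min(4L, max(2L, k)))
}

#' Color clustering configuration
#'
#' @param k integer number of clusters, or `"auto"` to call [choose_k()].
#' @param max_iterations Lloyd iteration cap.
#' @param tolerance advisory centroid-movement tolerance; iteration also
#'   stops when cluster assignments stabilize.
#' @param seed integer seed (deterministic initialization).
#' @return object of class `color_cluster_config`.
#' @export
color_cluster_config <- function(k = "auto", max_iterations = 100L,
                                 tolerance = 1e-4, seed = 1L) {
  if (is.numeric(k) && k < 1) stop("k must be >= 1")
  stopifnot(tolerance > 0, max_iterations >= 1)
  structure(list(k = k, max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, seed = as.integer(seed)),
            class = "color_cluster_config")
}

# Deterministic greedy farthest-color initialization: first center = color
# farthest from the mean color, each next = color farthest (min-distance)
# from the chosen set. Duplicate-free when possible.
.farthest_color_init <- function(colors, k) {
  X <- unique(colors)
  if (nrow(X) < k) X <- colors  # fall back, duplicated centers allowed
  ctrs <- matrix(0, k, 3L)
  d2 <- sqdist_to(colMeans(X), X)
  ctrs[1L, ] <- X[which.max(d2), ]
  if (k > 1L) {
    mind <- sqdist_to(ctrs[1L, ], X)
    for (j in 2:k) {
      ctrs[j, ] <- X[which.max(mind), ]
      mind <- pmin(mind, sqdist_to(ctrs[j, ], X))
    }
  }
  ctrs
}

#' K-means color denoising
#'
#' Clusters the per-point RGB feature matrix with Lloyd's algorithm
#' (deterministic greedy farthest-color initialization) and keeps the plant
#' clusters: those whose mean ExG exceeds the across-cluster mean of cluster
#' ExG means — the Excess Green operationalization of "the predominant green
#' vegetation". With k = 1 the whole cloud is returned.
#'
#' @param cloud a colored `point_cloud`.
#' @param cfg a [color_cluster_config()].
#' @return the retained `point_cloud`, order preserved. Attributes
#'   `cluster` (per-input-point cluster id) and `kept_clusters` expose the
#'   partition for inspection.
#' @export
kmeans_color_denoise <- function(cloud, cfg = color_cluster_config()) {
  k <- if (identical(cfg$k, "auto")) choose_k(cloud) else as.integer(cfg$k)
  n <- n_points(cloud)
  if (k > n) stop("k exceeds the number of points")
  X <- cloud$colors
  storage.mode(X) <- "double"
  k <- min(k, nrow(unique(X)))  # duplicate colors cannot seed distinct centers
  if (k == 1L) {
    out <- cloud
    attr(out, "cluster") <- rep(1L, n)
    attr(out, "kept_clusters") <- 1L
    return(out)
  }
  init <- local_rng(cfg$seed, .farthest_color_init(X, k))
  km <- suppressWarnings(stats::kmeans(X, centers = init,
                                       iter.max = cfg$max_iterations,
                                       algorithm = "Lloyd"))
  cl_exg <- vapply(seq_len(k), function(j) {
    ctr <- km$centers[j, ]
    2 * ctr[2] - ctr[1] - ctr[3]
  }, numeric(1L))
  kept <- which(cl_exg > mean(cl_exg))
  if (length(kept) == 0L) kept <- which.max(cl_exg)
  out <- cloud[km$cluster %in% kept]
  attr(out, "cluster") <- km$cluster
  attr(out, "kept_clusters") <- kept
  out
}
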