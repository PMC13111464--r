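# Fixtures built in code: small clouds, palettes, and independent oracles.

# A small random colored cloud.
random_cloud <- function(n, seed = 1L, extent = 100, labeled = FALSE) {
  withr::with_seed(seed, {
    point_cloud(matrix(runif(3L * n, 0, extent), ncol = 3L),
                matrix(sample(0:255, 3L * n, replace = TRUE), ncol = 3L),
                labels = if (labeled) sample(0:4, n, replace = TRUE))
  })
}

# A two-palette cloud: `n1` plant-green points followed by `n2` gray points.
two_palette_cloud <- function(n1 = 400L, n2 = 200L, seed = 1L,
                              green = c(40, 160, 40), gray = c(140, 140, 140),
                              sd = 8) {
  withr::with_seed(seed, {
    cols <- rbind(
      matrix(rnorm(3L * n1, rep(green, each = n1), sd), ncol = 3L),
      matrix(rnorm(3L * n2, rep(gray, each = n2), sd), ncol = 3L))
    cols <- matrix(as.integer(pmax(pmin(round(cols), 255), 0)), ncol = 3L)
    point_cloud(matrix(runif(3L * (n1 + n2), 0, 50), ncol = 3L), cols,
                labels = c(rep(2L, n1), rep(-1L, n2)))
  })
}

# Independent FPS oracle: greedy max-min over the full distance matrix.
fps_oracle <- function(coords, m, start = 1L) {
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))^2
  sel <- integer(m)
  sel[1L] <- start
  mind <- D[, start]
  if (m > 1L) for (j in 2:m) {
    nxt <- which.max(mind)  # which.max: lowest index on ties
    sel[j] <- nxt
    mind <- pmin(mind, D[, nxt])
  }
  sel
}

# Brute-force per-point metric recomputation (oracle for weighted metrics).
metrics_oracle <- function(true, pred, classes = 0:2) {
  out <- list()
  for (k in classes) {
    tp <- sum(true == k & pred == k)
    fp <- sum(true != k & pred == k)
    fn <- sum(true == k & pred != k)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    iou <- if (tp + fp + fn == 0) 0 else tp / (tp + fp + fn)
    out[[as.character(k)]] <- c(precision = prec, recall = rec, f1 = f1,
                                iou = iou, support = sum(true == k))
  }
  sup <- vapply(out, `[[`, numeric(1L), "support")
  w <- sup / sum(sup)
  list(per_class = out, weights = w,
       weighted_iou = sum(w * vapply(out, `[[`, numeric(1L), "iou")),
       weighted_f1 = sum(w * vapply(out, `[[`, numeric(1L), "f1")),
       overall_accuracy = mean(true == pred))
}
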