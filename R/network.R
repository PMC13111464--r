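# Compact hierarchical point-set segmentation network (a PointNet++-style
# encoder/decoder whose set-abstraction sampling layer is voxel-grid based).
#
# Implemented directly in R matrix algebra with hand-derived backpropagation:
# the geometric scaffolding of each cloud (sampling indices, ball-query
# groups, interpolation weights) is fixed by the cloud and the seed, so it is
# precomputed once per cloud; training then alternates dense/max-pool
# forward passes and their adjoints over that fixed structure, with Adam
# updates.

#' Set-abstraction level configuration
#'
#' @param n target centroid count N'.
#' @param radius_frac ball-query radius as a fraction of the cloud diameter.
#' @param K maximum neighbors per group.
#' @param h_widths hidden widths of the shared per-point MLP h.
#' @param out output feature width C' (the width of the MLP gamma applied
#'   after the coordinate-wise max).
#' @return list describing one SA level.
#' @export
sa_level_config <- function(n, radius_frac, K = 32L, h_widths = c(32L, 32L),
                            out = 64L) {
  stopifnot(n >= 1L, radius_frac > 0, K >= 1L, all(h_widths >= 1L), out >= 1L)
  list(n = as.integer(n), radius_frac = radius_frac, K = as.integer(K),
       h_widths = as.integer(h_widths), out = as.integer(out))
}

#' Network configuration
#'
#' Three set-abstraction levels with strictly decreasing centroid counts,
#' a feature-propagation decoder with inverse-distance interpolation over
#' `interp_k` neighbors, and a dropout classification head over the three
#' semantic organ classes. The sampling layer is voxel-grid downsampling by
#' default; `sampler = "fps"` swaps in farthest point sampling with no other
#' change (all downstream shapes are sampler-independent).
#'
#' @param sa_levels list of three [sa_level_config()]s, N' strictly
#'   decreasing.
#' @param fp_widths list of decoder MLP widths, one vector per propagation
#'   step (coarsest first).
#' @param interp_k interpolation neighbor count (default 3).
#' @param dropout dropout rate in the head, in \[0, 1).
#' @param n_classes number of semantic classes (default 3).
#' @param sampler `"vgds"` or `"fps"`.
#' @param use_colors also feed RGB (scaled to \[0, 1\]) as input features.
#' @param input_points point budget each cloud is resampled to.
#' @return object of class `network_config`.
#' @export
network_config <- function(sa_levels = list(
                             sa_level_config(1024L, 0.05, 32L, c(64L, 64L), 128L),
                             sa_level_config(256L, 0.1, 32L, c(128L, 128L), 256L),
                             sa_level_config(64L, 0.2, 32L, c(256L, 256L), 512L)),
                           fp_widths = list(c(256L), c(128L), c(128L, 64L)),
                           interp_k = 3L, dropout = 0.5, n_classes = 3L,
                           sampler = c("vgds", "fps"), use_colors = FALSE,
                           input_points = 20000L) {
  ns <- vapply(sa_levels, `[[`, integer(1L), "n")
  if (length(sa_levels) != 3L) stop("three SA levels expected")
  if (any(diff(ns) >= 0)) stop("centroid counts must be strictly decreasing")
  if (length(fp_widths) != 3L) stop("one width vector per propagation step")
  stopifnot(dropout >= 0, dropout < 1, interp_k >= 1L)
  structure(list(sa_levels = sa_levels, fp_widths = fp_widths,
                 interp_k = as.integer(interp_k), dropout = dropout,
                 n_classes = as.integer(n_classes),
                 sampler = match.arg(sampler),
                 use_colors = isTRUE(use_colors),
                 input_points = as.integer(input_points)),
            class = "network_config")
}

#' Desk-scale network preset
#'
#' A small configuration (1,024 input points, reduced widths) sized so the
#' full train/evaluate loop runs on a laptop CPU in seconds per epoch; the
#' configuration exercised by the test suite.
#' @param sampler `"vgds"` (default) or `"fps"`.
#' @return a [network_config()].
#' @export
desk_network_config <- function(sampler = "vgds") {
  network_config(
    sa_levels = list(sa_level_config(256L, 0.1, 48L, c(48L, 48L), 96L),
                     sa_level_config(64L, 0.2, 32L, c(96L, 96L), 160L),
                     sa_level_config(16L, 0.4, 16L, c(160L, 160L), 160L)),
    fp_widths = list(c(160L), c(96L), c(64L, 32L)),
    sampler = sampler, input_points = 1024L)
}

#' Training configuration
#'
#' Adam with L2 weight decay, stepwise learning-rate halving, dropout in the
#' head, and early stopping on validation mean IoU.
#'
#' @param batch_size clouds per Adam update (gradient accumulation).
#' @param lr initial learning rate.
#' @param weight_decay L2 coefficient.
#' @param lr_decay_factor multiplicative decay (default 0.5).
#' @param lr_step epochs between decays (default 20).
#' @param dropout dropout rate (overrides the network config).
#' @param epochs training epoch cap.
#' @param patience early-stopping patience on validation mIoU (evaluations
#'   without improvement before stopping).
#' @param seed integer seed governing initialization, shuffling, sampling
#'   and dropout.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 7L, lr = 1e-4, weight_decay = 1e-4,
                         lr_decay_factor = 0.5, lr_step = 20L, dropout = 0.5,
                         epochs = 100L, patience = 10L, seed = 1L) {
  stopifnot(lr >= 0, weight_decay >= 0, lr_decay_factor > 0, patience >= 1L,
            epochs >= 1L, batch_size >= 1L, dropout >= 0, dropout < 1)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay,
                 lr_decay_factor = lr_decay_factor,
                 lr_step = as.integer(lr_step), dropout = dropout,
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training preset
#'
#' Per-cloud updates at a learning rate matched to the desk network's size;
#' used by the test suite's overfit sanity runs.
#' @param epochs epoch cap (default 60).
#' @param seed integer seed.
#' @return a [train_config()].
#' @export
desk_train_config <- function(epochs = 60L, seed = 1L) {
  train_config(batch_size = 1L, lr = 3e-3, lr_step = 25L, dropout = 0.3,
               epochs = epochs, patience = epochs, seed = seed)
}

## ---- geometric scaffolding --------------------------------------------

#' Sampling layer: choose SA centroids
#'
#' Selects exactly `n` centroids from the points, by voxel-grid downsampling
#' matched to the exact count (`sampler = "vgds"`, nearest-to-centroid
#' representatives so centroids are original points) or by farthest point
#' sampling. Deterministic under `seed`.
#'
#' @param coords m x 3 coordinate matrix.
#' @param n centroid count (<= m).
#' @param seed integer seed.
#' @param sampler `"vgds"` or `"fps"`.
#' @return integer vector of `n` row indices into `coords`.
#' @export
sa_sample <- function(coords, n, seed = 1L, sampler = c("vgds", "fps")) {
  sampler <- match.arg(sampler)
  m <- nrow(coords)
  if (n > m) stop("centroid count exceeds point count")
  if (n == m) return(seq_len(m))
  pc <- point_cloud(coords, matrix(0L, m, 3L))
  if (sampler == "vgds") {
    match_voxel_size_to_count(pc, n, seed = seed,
                              representative = "nearest_to_centroid"
                              )$result$indices
  } else {
    farthest_point_sample(pc, fps_config(n))$indices
  }
}

#' Grouping layer: ball query with relative coordinates
#'
#' For each centroid, takes the up-to-K nearest points within the radius
#' (the centroid itself always qualifies at distance zero) and expresses
#' their coordinates relative to the centroid. Groups short of K are padded
#' by repeating their centroid-nearest member, so every group has exactly K
#' rows.
#'
#' @param coords m x 3 matrix of candidate points.
#' @param centroid_idx integer indices of the centroids within `coords`.
#' @param radius ball radius in the coordinate units.
#' @param K group size.
#' @return list: `idx` (n x K index matrix into `coords`), `rel`
#'   ((n*K) x 3 relative coordinates, rows grouped centroid-major).
#' @export
sa_group <- function(coords, centroid_idx, radius, K) {
  stopifnot(radius > 0, K >= 1L)
  n <- length(centroid_idx)
  idx <- matrix(0L, n, K)
  r2 <- radius^2
  for (i in seq_len(n)) {
    d2 <- sqdist_to(coords[centroid_idx[i], ], coords)
    within <- which(d2 <= r2)
    within <- within[order(d2[within])]  # nearest first; centroid is first
    if (length(within) >= K) {
      idx[i, ] <- within[seq_len(K)]
    } else {
      idx[i, ] <- c(within, rep(within[1L], K - length(within)))
    }
  }
  flat <- as.vector(t(idx))
  rel <- coords[flat, , drop = FALSE] -
    coords[rep(centroid_idx, each = K), , drop = FALSE]
  list(idx = idx, rel = rel)
}

# Inverse-distance-weighted interpolation matrix: fine x coarse sparse
# weights over the k nearest coarse points; a fine point coincident with a
# coarse point takes that point's feature exactly (weight collapse).
interp_matrix <- function(coarse_coords, fine_coords, k = 3L) {
  nf <- nrow(fine_coords); nc <- nrow(coarse_coords)
  k <- min(k, nc)
  ii <- integer(nf * k); jj <- integer(nf * k); ww <- numeric(nf * k)
  for (i in seq_len(nf)) {
    d2 <- sqdist_to(fine_coords[i, ], coarse_coords)
    nb <- order(d2)[seq_len(k)]
    d2n <- d2[nb]
    if (d2n[1L] < 1e-20) {
      w <- c(1, rep(0, k - 1L))
    } else {
      w <- 1 / d2n
      w <- w / sum(w)
    }
    rng <- ((i - 1L) * k + 1L):(i * k)
    ii[rng] <- i; jj[rng] <- nb; ww[rng] <- w
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(nf, nc))
}

#' Feature propagation: interpolate, skip-concatenate, transform
#'
#' Inverse-distance-weighted interpolation of coarse features onto fine
#' points over the `k` nearest coarse centroids, optionally concatenated
#' with the fine level's own (skip) features and passed through a shared
#' MLP when `params` are supplied.
#'
#' @param coarse_coords,coarse_feats coarse centroid positions and features.
#' @param fine_coords target positions.
#' @param skip_feats optional fine-level features to concatenate.
#' @param params optional list of dense layers (`list(list(W, b), ...)`).
#' @param k interpolation neighbor count.
#' @return fine-level feature matrix.
#' @export
fp_decode <- function(coarse_coords, coarse_feats, fine_coords,
                      skip_feats = NULL, params = NULL, k = 3L) {
  P <- interp_matrix(as.matrix(coarse_coords), as.matrix(fine_coords), k)
  F <- as.matrix(P %*% coarse_feats)
  if (!is.null(skip_feats)) F <- cbind(F, skip_feats)
  if (!is.null(params))
    for (ly in params) F <- pmax(sweep(F %*% ly$W, 2L, ly$b, `+`), 0)
  F
}

## ---- parameters -------------------------------------------------------

init_dense <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)),
                  n_in, n_out),
       b = numeric(n_out))
}

# Flat named parameter list: "<block>.W" / "<block>.b".
init_params <- function(config, in_feat_dim, seed) {
  local_rng(seed, {
    p <- list()
    add <- function(p, name, n_in, n_out) {
      d <- init_dense(n_in, n_out)
      p[[paste0(name, ".W")]] <- d$W
      p[[paste0(name, ".b")]] <- d$b
      p
    }
    C <- in_feat_dim
    for (l in seq_along(config$sa_levels)) {
      lv <- config$sa_levels[[l]]
      d_in <- 3L + C
      for (j in seq_along(lv$h_widths)) {
        p <- add(p, sprintf("sa%d.h%d", l, j), d_in, lv$h_widths[j])
        d_in <- lv$h_widths[j]
      }
      p <- add(p, sprintf("sa%d.g", l), d_in, lv$out)
      C <- lv$out
    }
    outs <- vapply(config$sa_levels, `[[`, integer(1L), "out")
    skips <- c(in_feat_dim, outs[1L], outs[2L])  # skip widths, fine to coarse
    C <- outs[3L]
    for (s in 1:3) {  # s = 1 coarsest propagation step
      d_in <- C + skips[4L - s]
      for (j in seq_along(config$fp_widths[[s]])) {
        p <- add(p, sprintf("fp%d.m%d", s, j), d_in, config$fp_widths[[s]][j])
        d_in <- config$fp_widths[[s]][j]
      }
      C <- d_in
    }
    p <- add(p, "head", C, config$n_classes)
    p
  })
}

## ---- per-cloud structure ----------------------------------------------

# Resample a labeled cloud to the configured budget, normalize (centroid at
# the origin, unit max radius), and precompute sampling indices, groups and
# interpolation matrices for every level.
build_graph <- function(cloud, config, seed = 1L) {
  n <- config$input_points
  if (n_points(cloud) < n)
    stop("cloud has fewer points than the input budget")
  # normalize BEFORE resampling: translation then cancels exactly, so the
  # voxel grid (anchored at the min corner of the normalized cloud) and
  # everything downstream are rigid-translation invariant
  ctr <- colMeans(cloud$coords)
  scale <- max(sqrt(rowSums(sweep(cloud$coords, 2L, ctr)^2)))
  if (scale == 0) scale <- 1
  norm_cloud <- cloud
  norm_cloud$coords <- sweep(cloud$coords, 2L, ctr) / scale
  base <- if (n_points(cloud) == n) norm_cloud else {
    if (config$sampler == "vgds")
      match_voxel_size_to_count(norm_cloud, n, seed = seed,
                                representative = "nearest_to_centroid")$result$cloud
    else
      farthest_point_sample(norm_cloud, fps_config(n))$cloud
  }
  coords <- base$coords
  feats <- coords
  if (config$use_colors) feats <- cbind(feats, base$colors / 255)
  diam <- cloud_diameter(coords)
  levels <- list()
  prev_coords <- coords
  for (l in 1:3) {
    lv <- config$sa_levels[[l]]
    ci <- sa_sample(prev_coords, lv$n, seed = derive_seed(seed, l),
                    sampler = config$sampler)
    radius <- lv$radius_frac * diam
    grp <- sa_group(prev_coords, ci, radius, lv$K)
    cc <- prev_coords[ci, , drop = FALSE]
    # relative coordinates normalized by the ball radius: keeps every
    # level's geometric input on a comparable scale
    levels[[l]] <- list(centroid_idx = ci, idx = grp$idx,
                        rel = grp$rel / radius, coords = cc, K = lv$K)
    prev_coords <- cc
  }
  # interpolation matrices, coarsest step first: level3 -> level2 -> 1 -> 0
  interp <- list(
    interp_matrix(levels[[3L]]$coords, levels[[2L]]$coords, config$interp_k),
    interp_matrix(levels[[2L]]$coords, levels[[1L]]$coords, config$interp_k),
    interp_matrix(levels[[1L]]$coords, coords, config$interp_k))
  list(coords = coords, feats = feats, levels = levels, interp = interp,
       labels = base$labels, base_cloud = base,
       center = ctr, scale = scale)
}

## ---- forward / backward -----------------------------------------------

dense_fwd <- function(X, p, name, relu = TRUE) {
  Z <- sweep(X %*% p[[paste0(name, ".W")]], 2L, p[[paste0(name, ".b")]], `+`)
  if (relu) list(out = pmax(Z, 0), pre = Z, X = X) else
    list(out = Z, pre = Z, X = X)
}

dense_bwd <- function(cache, dOut, p, name, grads, relu = TRUE) {
  dZ <- if (relu) dOut * (cache$pre > 0) else dOut
  grads[[paste0(name, ".W")]] <- grads[[paste0(name, ".W")]] +
    crossprod(cache$X, dZ)
  grads[[paste0(name, ".b")]] <- grads[[paste0(name, ".b")]] + colSums(dZ)
  list(dX = dZ %*% t(p[[paste0(name, ".W")]]), grads = grads)
}

# Max over K group members, rows centroid-major: returns n x C maxima and
# the argmax row offsets for the adjoint.
group_max <- function(H, n, K) {
  C <- ncol(H)
  M <- H[seq.int(1L, by = K, length.out = n), , drop = FALSE]
  A <- matrix(1L, n, C)
  if (K > 1L) for (k in 2:K) {
    Hk <- H[seq.int(k, by = K, length.out = n), , drop = FALSE]
    imp <- Hk > M
    M[imp] <- Hk[imp]
    A[imp] <- k
  }
  list(M = M, A = A)
}

group_max_bwd <- function(dM, A, n, K, C) {
  dH <- matrix(0, n * K, C)
  rows <- (seq_len(n) - 1L) * K + A       # n x C matrix of row indices
  dH[cbind(as.vector(rows), rep(seq_len(C), each = n))] <- as.vector(dM)
  dH
}

network_forward <- function(params, config, graph, train = FALSE,
                            dropout = 0, dropout_seed = 1L) {
  caches <- list()
  F <- graph$feats
  enc <- list(F)  # encoder features per level (level0 first)
  for (l in 1:3) {
    lv <- config$sa_levels[[l]]
    g <- graph$levels[[l]]
    X <- cbind(g$rel, F[as.vector(t(g$idx)), , drop = FALSE])
    hc <- list()
    for (j in seq_along(lv$h_widths)) {
      c1 <- dense_fwd(X, params, sprintf("sa%d.h%d", l, j))
      hc[[j]] <- c1
      X <- c1$out
    }
    mx <- group_max(X, lv$n, g$K)
    gc <- dense_fwd(mx$M, params, sprintf("sa%d.g", l))
    F <- gc$out
    enc[[l + 1L]] <- F
    caches[[sprintf("sa%d", l)]] <- list(h = hc, mx = mx, g = gc,
                                         idx = g$idx, K = g$K, n = lv$n)
  }
  D <- enc[[4L]]
  for (s in 1:3) {
    P <- graph$interp[[s]]
    I <- as.matrix(P %*% D)
    skip <- enc[[4L - s]]
    X <- cbind(I, skip)
    mc <- list()
    for (j in seq_along(config$fp_widths[[s]])) {
      c1 <- dense_fwd(X, params, sprintf("fp%d.m%d", s, j))
      mc[[j]] <- c1
      X <- c1$out
    }
    caches[[sprintf("fp%d", s)]] <- list(m = mc, ncoarse = ncol(I))
    D <- X
  }
  if (train && dropout > 0) {
    mask <- local_rng(dropout_seed,
                      matrix(stats::runif(length(D)) >= dropout,
                             nrow(D), ncol(D))) / (1 - dropout)
    D <- D * mask
    caches$dropout_mask <- mask
  }
  hc <- dense_fwd(D, params, "head", relu = FALSE)
  caches$head <- hc
  logits <- hc$out
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(logits = logits, probs = probs, caches = caches)
}

# Weighted softmax cross-entropy; returns loss and dlogits.
ce_loss <- function(probs, labels, class_weights) {
  n <- nrow(probs)
  iy <- cbind(seq_len(n), labels + 1L)
  w <- class_weights[labels + 1L]
  loss <- -sum(w * log(pmax(probs[iy], 1e-12))) / sum(w)
  dl <- probs * w
  dl[iy] <- dl[iy] - w
  list(loss = loss, dlogits = dl / sum(w))
}

network_backward <- function(params, config, graph, caches, dlogits) {
  grads <- lapply(params, function(x) if (is.matrix(x))
    matrix(0, nrow(x), ncol(x)) else numeric(length(x)))
  bk <- dense_bwd(caches$head, dlogits, params, "head", grads, relu = FALSE)
  grads <- bk$grads
  dD <- bk$dX
  if (!is.null(caches$dropout_mask)) dD <- dD * caches$dropout_mask
  denc <- vector("list", 4L)  # gradient w.r.t. encoder outputs (skip paths)
  for (s in 3:1) {
    fc <- caches[[sprintf("fp%d", s)]]
    for (j in rev(seq_along(config$fp_widths[[s]]))) {
      bk <- dense_bwd(fc$m[[j]], dD, params, sprintf("fp%d.m%d", s, j), grads)
      grads <- bk$grads
      dD <- bk$dX
    }
    nc <- fc$ncoarse
    dI <- dD[, seq_len(nc), drop = FALSE]
    dskip <- dD[, -seq_len(nc), drop = FALSE]
    lvl <- 4L - s
    denc[[lvl]] <- if (is.null(denc[[lvl]])) dskip else denc[[lvl]] + dskip
    dD <- as.matrix(Matrix::crossprod(graph$interp[[s]], dI))
  }
  denc[[4L]] <- dD  # gradient reaching the coarsest encoder output
  dF <- denc[[4L]]
  for (l in 3:1) {
    sc <- caches[[sprintf("sa%d", l)]]
    bk <- dense_bwd(sc$g, dF, params, sprintf("sa%d.g", l), grads)
    grads <- bk$grads
    dM <- bk$dX
    dH <- group_max_bwd(dM, sc$mx$A, sc$n, sc$K, ncol(dM))
    for (j in rev(seq_along(sc$h))) {
      bk <- dense_bwd(sc$h[[j]], dH, params, sprintf("sa%d.h%d", l, j), grads)
      grads <- bk$grads
      dH <- bk$dX
    }
    # dH columns: first 3 are relative coordinates (inputs, no gradient
    # needed); the rest flow back to the previous level's features.
    if (ncol(dH) > 3L) {
      dFeat <- dH[, -(1:3), drop = FALSE]
      nprev <- if (l == 1L) nrow(graph$feats) else config$sa_levels[[l - 1L]]$n
      dPrev <- matrix(0, nprev, ncol(dFeat))
      flat <- as.vector(t(sc$idx))
      dPrev <- rowsum(dFeat, group = flat,
                      reorder = FALSE)
      rows <- as.integer(rownames(dPrev))
      full <- matrix(0, nprev, ncol(dFeat))
      full[rows, ] <- dPrev
      dF <- full
    } else {
      dF <- matrix(0, if (l == 1L) nrow(graph$feats)
                   else config$sa_levels[[l - 1L]]$n, 0L)
    }
    if (!is.null(denc[[l]]) && ncol(dF) == ncol(denc[[l]]))
      dF <- dF + denc[[l]]
    else if (!is.null(denc[[l]])) dF <- denc[[l]]
  }
  grads
}

## ---- optimizer --------------------------------------------------------

adam_init <- function(params)
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)

adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    p <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (is.matrix(p)) dimnames(p) <- NULL else names(p) <- NULL
    params[[nm]] <- p
  }
  list(params = params, state = state)
}

## ---- model ------------------------------------------------------------

#' Create an untrained segmentation model
#'
#' @param config a [network_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class `vgds_pointnet`.
#' @export
segmentation_model <- function(config = desk_network_config(), seed = 1L) {
  in_dim <- 3L + if (config$use_colors) 3L else 0L
  structure(list(config = config,
                 params = init_params(config, in_dim, seed),
                 trained = FALSE, history = NULL,
                 class_weights = rep(1, config$n_classes),
                 seed = as.integer(seed)),
            class = "vgds_pointnet")
}

#' @export
print.vgds_pointnet <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1L)))
  cat(sprintf("<vgds_pointnet> %s sampler, %d input points, %.0f parameters, %s\n",
              x$config$sampler, x$config$input_points, np,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

cloud_miou <- function(true, pred, n_classes = 3L) {
  ious <- vapply(seq_len(n_classes) - 1L, function(k) {
    tp <- sum(true == k & pred == k)
    un <- sum(true == k | pred == k)
    if (un == 0) NA_real_ else tp / un
  }, numeric(1L))
  mean(ious, na.rm = TRUE)
}

#' Train the segmentation network
#'
#' Minimizes inverse-support-weighted cross-entropy over the three semantic
#' classes with Adam (L2 weight decay, stepwise learning-rate halving,
#' dropout in the head), evaluating mean IoU on the validation clouds after
#' every epoch and stopping early when it fails to improve for `patience`
#' evaluations; the best-validation parameters are restored.
#'
#' @param model a [segmentation_model()].
#' @param train_clouds list of labeled `point_cloud`s (leaf instances are
#'   collapsed to the semantic class automatically).
#' @param val_clouds list of labeled validation clouds (held-out plants).
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return the trained model; `history` holds one row per epoch (`epoch`,
#'   `loss`, `accuracy`, `val_miou`, `lr`).
#' @export
train_model <- function(model, train_clouds, val_clouds = list(),
                        cfg = desk_train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "vgds_pointnet"), inherits(cfg, "train_config"))
  if (length(train_clouds) == 0L) stop("empty training split")
  config <- model$config
  prep <- function(cl, i) {
    cl <- collapse_labels(cl)
    build_graph(cl, config, seed = derive_seed(cfg$seed, i))
  }
  tg <- lapply(seq_along(train_clouds),
               function(i) prep(train_clouds[[i]], i))
  vg <- lapply(seq_along(val_clouds),
               function(i) prep(val_clouds[[i]], 10000L + i))
  all_lab <- unlist(lapply(tg, `[[`, "labels"))
  sup <- vapply(seq_len(config$n_classes) - 1L,
                function(k) sum(all_lab == k), numeric(1L))
  if (any(sup == 0)) sup[sup == 0] <- 1
  w <- (sum(sup) / sup)
  model$class_weights <- w / mean(w)

  params <- model$params
  state <- adam_init(params)
  lr <- cfg$lr
  hist <- list()
  best_miou <- -Inf
  best_params <- params
  stall <- 0L
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    if (ep > 1L && cfg$lr_step > 0L && (ep - 1L) %% cfg$lr_step == 0L)
      lr <- lr * cfg$lr_decay_factor
    ord <- local_rng(derive_seed(cfg$seed, 500L + ep),
                     sample(seq_along(tg)))
    ep_loss <- 0; ep_correct <- 0; ep_n <- 0
    i <- 1L
    while (i <= length(ord)) {
      batch <- ord[i:min(i + cfg$batch_size - 1L, length(ord))]
      i <- i + cfg$batch_size
      acc_grads <- NULL
      for (b in batch) {
        g <- tg[[b]]
        step <- step + 1L
        fw <- network_forward(params, config, g, train = TRUE,
                              dropout = cfg$dropout,
                              dropout_seed = derive_seed(cfg$seed, 7000L + step))
        ls <- ce_loss(fw$probs, g$labels, model$class_weights)
        ep_loss <- ep_loss + ls$loss
        pred <- max.col(fw$probs) - 1L
        ep_correct <- ep_correct + sum(pred == g$labels)
        ep_n <- ep_n + length(g$labels)
        gr <- network_backward(params, config, g, fw$caches, ls$dlogits)
        acc_grads <- if (is.null(acc_grads)) gr else
          Map(`+`, acc_grads, gr)
      }
      acc_grads <- lapply(acc_grads, `/`, length(batch))
      upd <- adam_step(params, acc_grads, state, lr, cfg$weight_decay)
      params <- upd$params
      state <- upd$state
    }
    val_miou <- if (length(vg)) {
      mean(vapply(vg, function(g) {
        fw <- network_forward(params, config, g, train = FALSE)
        cloud_miou(g$labels, max.col(fw$probs) - 1L, config$n_classes)
      }, numeric(1L)))
    } else NA_real_
    hist[[ep]] <- data.frame(epoch = ep, loss = ep_loss / length(tg),
                             accuracy = ep_correct / ep_n,
                             val_miou = val_miou, lr = lr)
    if (verbose)
      cat(sprintf("epoch %3d  loss %.4f  acc %.4f  val mIoU %s  lr %.2g\n",
                  ep, ep_loss / length(tg), ep_correct / ep_n,
                  ifelse(is.na(val_miou), "-", sprintf("%.4f", val_miou)), lr))
    if (length(vg)) {
      if (val_miou > best_miou + 1e-9) {
        best_miou <- val_miou
        best_params <- params
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    } else {
      best_params <- params
    }
  }
  model$params <- best_params
  model$trained <- TRUE
  model$history <- do.call(rbind, hist)
  model$train_config <- cfg
  model
}

#' Segment a cloud with a trained model
#'
#' The cloud is resampled to the model's input budget with the model's
#' sampler, normalized (translation to the centroid, unit max radius),
#' scored by the network, and the predicted labels are propagated back to
#' every original point through its nearest resampled neighbor. Scores sum
#' to one per point.
#'
#' @param object a trained `vgds_pointnet`.
#' @param cloud a `point_cloud`.
#' @param budget optional override of the input point budget.
#' @param seed seed for the resampling draw.
#' @param ... unused.
#' @return list: `labels` (one class id per input point), `scores` (n x
#'   n_classes matrix, rows sum to 1), `sampled_idx_labels` (labels at the
#'   resampled points).
#' @export
predict.vgds_pointnet <- function(object, cloud, budget = NULL, seed = 1L,
                                  ...) {
  if (!object$trained) stop("model is untrained; call train_model() first")
  config <- object$config
  if (!is.null(budget)) config$input_points <- as.integer(budget)
  graph <- build_graph(cloud, config, seed = seed)
  fw <- network_forward(object$params, config, graph, train = FALSE)
  sample_labels <- max.col(fw$probs) - 1L
  # propagate to all original points via nearest resampled neighbor
  orig <- sweep(cloud$coords, 2L, graph$center) / graph$scale
  nn <- integer(nrow(orig))
  chunk <- 2048L
  sc <- graph$coords
  for (s in seq(1L, nrow(orig), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(orig))
    block <- orig[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rep(1, nrow(sc))) -
      2 * block %*% t(sc) + outer(rep(1, e - s + 1L), rowSums(sc^2))
    nn[s:e] <- max.col(-d2)
  }
  list(labels = sample_labels[nn],
       scores = fw$probs[nn, , drop = FALSE],
       sampled_idx_labels = sample_labels,
       sampled_probs = fw$probs)
}

#' Save or restore a model checkpoint
#'
#' The checkpoint is the model object itself — network configuration,
#' weights, class weights and training history — serialized with
#' [saveRDS()], so a restored model is immediately usable for
#' [predict.vgds_pointnet()].
#'
#' @param model a `vgds_pointnet` model.
#' @param path checkpoint file path.
#' @return `save_model` returns `invisible(path)`; `load_model` returns the
#'   restored model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "vgds_pointnet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "vgds_pointnet"))
    stop("not a phenopoint model checkpoint: ", path)
  model
}

#' Shared-MLP set encoder (the symmetric-function building block)
#'
#' Applies the shared per-point MLP h to every row of a grouped neighborhood
#' matrix, takes the coordinate-wise max over each group, and applies the
#' MLP gamma — a symmetric function of the group, invariant to any
#' permutation or duplication of its members.
#'
#' @param grouped (n*K) x d matrix of grouped per-point inputs, rows
#'   centroid-major.
#' @param n,K group count and group size.
#' @param h_layers,g_layer dense parameter lists (`list(W, b)`); `h_layers`
#'   is a list of such layers.
#' @return n x ncol(g_layer$W) encoded features.
#' @export
sa_encode <- function(grouped, n, K, h_layers, g_layer) {
  X <- grouped
  for (ly in h_layers) X <- pmax(sweep(X %*% ly$W, 2L, ly$b, `+`), 0)
  M <- group_max(X, n, K)$M
  pmax(sweep(M %*% g_layer$W, 2L, g_layer$b, `+`), 0)
}
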