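tiny_config <- function(sampler = "vgds") {
  network_config(
    sa_levels = list(sa_level_config(16L, 0.3, 8L, c(8L, 8L), 12L),
                     sa_level_config(8L, 0.5, 8L, c(12L, 12L), 16L),
                     sa_level_config(4L, 0.8, 4L, c(16L, 16L), 16L)),
    fp_widths = list(c(12L), c(12L), c(8L)), input_points = 64L,
    sampler = sampler)
}

tiny_cloud <- function(seed = 3)
  collapse_labels(generate_plant(plant_spec(points_per_mm2 = 0.05,
                                            seed = seed))$cloud)

test_that("the set encoder is a symmetric function of its group", {
  withr::with_seed(1, {
    h <- list(phenopoint:::init_dense(6, 8), phenopoint:::init_dense(8, 8))
    g <- phenopoint:::init_dense(8, 5)
    grouped <- matrix(rnorm(2 * 7 * 6), 14, 6)  # 2 groups of K = 7
  })
  base <- sa_encode(grouped, 2L, 7L, h, g)
  # permuting points within each group leaves the encoding unchanged
  perm <- withr::with_seed(2, c(sample(1:7), 7 + sample(1:7)))
  expect_equal(sa_encode(grouped[perm, ], 2L, 7L, h, g), base)
  # duplicating members never changes the encoding (max idempotence):
  # two different paddings of the same underlying set agree
  expect_equal(sa_encode(rbind(grouped[c(1, 1, 1, 4:7), ], grouped[8:14, ]),
                         2L, 7L, h, g),
               sa_encode(rbind(grouped[c(1, 4, 5, 6, 7, 7, 7), ],
                               grouped[8:14, ]), 2L, 7L, h, g),
               tolerance = 1e-12, ignore_attr = TRUE)
  # single-member group: encoder output is gamma(h(x))
  x <- grouped[1, , drop = FALSE]
  single <- sa_encode(x[rep(1, 7), , drop = FALSE], 1L, 7L, h, g)
  relu <- function(z) pmax(z, 0)
  manual <- relu(sweep(relu(sweep(relu(sweep(x %*% h[[1]]$W, 2, h[[1]]$b,
                                             `+`)) %*% h[[2]]$W, 2,
                                  h[[2]]$b, `+`)) %*% g$W, 2, g$b, `+`))
  expect_equal(single, manual)
})

test_that("ball-query grouping respects radii and pads short groups", {
  # two clusters 100 mm apart, radius 10: no cross-cluster membership
  withr::with_seed(4, {
    a <- matrix(rnorm(60, sd = 2), ncol = 3)
    b <- matrix(rnorm(60, sd = 2), ncol = 3)
  })
  b[, 1] <- b[, 1] + 100
  coords <- rbind(a, b)
  grp <- sa_group(coords, centroid_idx = c(1L, 21L), radius = 10, K = 30)
  expect_true(all(grp$idx[1, ] <= 20))
  expect_true(all(grp$idx[2, ] >= 21))
  # the centroid is its own first neighbor with relative coordinate 0
  expect_equal(grp$idx[, 1], c(1L, 21L))
  expect_equal(grp$rel[1, ], c(0, 0, 0))
  expect_equal(grp$rel[31, ], c(0, 0, 0))
  # radius covering everything with K >= N: every group is the whole cloud
  small <- coords[1:15, ]
  g2 <- sa_group(small, 1:2, radius = 1e4, K = 15L)
  expect_setequal(g2$idx[1, ], 1:15)
  expect_setequal(g2$idx[2, ], 1:15)
  # fewer than K in the ball: padded by the centroid-nearest member
  g3 <- sa_group(coords, 1L, radius = 10, K = 25L)
  expect_equal(sum(g3$idx == g3$idx[1, 1]), 25L - 20L + 1L)
})

test_that("the sampling layer returns exact counts and sits in the hull", {
  withr::with_seed(5, coords <- matrix(runif(3 * 300), ncol = 3))
  expect_identical(sa_sample(coords, 300L), seq_len(300L))
  i1 <- sa_sample(coords, 1L, seed = 2)
  expect_length(i1, 1L)
  expect_true(all(coords[i1, ] >= 0 & coords[i1, ] <= 1))
  # voxel-matched centroids are more evenly spaced than random picks
  withr::with_seed(6, cube <- matrix(runif(3 * 4096), ncol = 3))
  vi <- sa_sample(cube, 512L, seed = 3)
  nnd <- function(idx) {
    pts <- cube[idx, ]
    apply(as.matrix(stats::dist(pts)), 1, function(r) min(r[r > 0]))
  }
  cv <- function(v) stats::sd(v) / mean(v)
  cv_v <- cv(nnd(vi))
  cv_r <- cv(nnd(withr::with_seed(8, sample(4096, 512))))
  expect_lt(cv_v, cv_r)
})

test_that("feature propagation interpolates by inverse distance", {
  coarse <- rbind(c(0, 0, 0), c(10, 0, 0))
  feats <- rbind(c(1, 5), c(3, -5))
  # coincident point inherits the centroid feature exactly
  out <- fp_decode(coarse, feats, rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(out, feats)
  # all coarse features equal: all interpolations equal
  same <- rbind(c(2, 2), c(2, 2))
  out2 <- fp_decode(coarse, same, matrix(runif(9), 3, 3))
  expect_true(all(abs(out2 - 2) < 1e-12))
  # midpoint of two equidistant centroids: the mean of their features
  mid <- fp_decode(coarse, feats, matrix(c(5, 0, 0), 1))
  expect_equal(as.numeric(mid), c(2, 0))
})

test_that("levels contract shapes and the sampler toggle changes none", {
  cl <- tiny_cloud()
  params <- phenopoint:::init_params(tiny_config(), 3L, seed = 2)
  dims <- lapply(c("vgds", "fps"), function(smp) {
    cfg <- tiny_config(smp)
    graph <- phenopoint:::build_graph(cl, cfg, seed = 5)
    fw <- phenopoint:::network_forward(params, cfg, graph)
    c(list(logits = dim(fw$logits)),
      lapply(fw$caches[c("sa1", "sa2", "sa3")],
             function(s) dim(s$g$out)))
  })
  # strictly decreasing centroid counts with configured widths
  expect_equal(dims[[1]]$sa1, c(16L, 12L))
  expect_equal(dims[[1]]$sa2, c(8L, 16L))
  expect_equal(dims[[1]]$sa3, c(4L, 16L))
  expect_equal(dims[[1]]$logits, c(64L, 3L))
  # swapping VGDS for FPS changes only the sampling layer, no shapes
  expect_identical(dims[[1]], dims[[2]])
})

test_that("backpropagation matches central finite differences", {
  cfg <- tiny_config()
  cl <- tiny_cloud(seed = 9)
  graph <- phenopoint:::build_graph(cl, cfg, seed = 5)
  params <- phenopoint:::init_params(cfg, 3L, seed = 2)
  lossf <- function(p) {
    fw <- phenopoint:::network_forward(p, cfg, graph)
    phenopoint:::ce_loss(fw$probs, graph$labels, c(1, 1.5, 0.7))$loss
  }
  fw <- phenopoint:::network_forward(params, cfg, graph)
  ls <- phenopoint:::ce_loss(fw$probs, graph$labels, c(1, 1.5, 0.7))
  gr <- phenopoint:::network_backward(params, cfg, graph, fw$caches,
                                      ls$dlogits)
  eps <- 1e-6
  for (nm in c("sa1.h1.W", "sa2.g.W", "fp1.m1.W", "head.W", "fp3.m1.b")) {
    ix <- withr::with_seed(3, sample(length(params[[nm]]), 2))
    for (i in ix) {
      pp <- params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      up <- lossf(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      dn <- lossf(pp)
      fd <- (up - dn) / (2 * eps)
      expect_equal(gr[[nm]][i], fd, tolerance = 1e-4)
    }
  }
})

test_that("loss decreases over the first training steps at lr 1e-4", {
  cl <- collapse_labels(generate_plant(plant_spec(points_per_mm2 = 0.15,
                                                  seed = 2))$cloud)
  for (sd in 1:3) {
    cfg <- desk_network_config()
    graph <- phenopoint:::build_graph(cl, cfg, seed = sd)
    params <- phenopoint:::init_params(cfg, 3L, seed = sd)
    state <- phenopoint:::adam_init(params)
    losses <- numeric(6)
    for (st in 1:6) {
      fw <- phenopoint:::network_forward(params, cfg, graph)
      ls <- phenopoint:::ce_loss(fw$probs, graph$labels, c(1, 1, 1))
      losses[st] <- ls$loss
      gr <- phenopoint:::network_backward(params, cfg, graph, fw$caches,
                                          ls$dlogits)
      upd <- phenopoint:::adam_step(params, gr, state, 1e-4, 1e-4)
      params <- upd$params
      state <- upd$state
    }
    expect_true(all(diff(losses[1:6]) < 0))
  }
})

test_that("zero learning rate freezes parameters; early stopping obeys patience", {
  cl <- tiny_cloud(seed = 4)
  model <- segmentation_model(tiny_config(), seed = 1)
  cfg0 <- train_config(batch_size = 1L, lr = 0, weight_decay = 0,
                       dropout = 0, epochs = 3L, patience = 5L, seed = 1L)
  trained <- train_model(model, list(cl), list(), cfg0)
  expect_equal(trained$params, model$params)
  expect_equal(diff(range(trained$history$loss)), 0)
  # constant validation mIoU with patience 1: stops after 2 evaluations
  cfg1 <- train_config(batch_size = 1L, lr = 0, weight_decay = 0,
                       dropout = 0, epochs = 10L, patience = 1L, seed = 1L)
  t2 <- train_model(model, list(cl), list(tiny_cloud(seed = 6)), cfg1)
  expect_equal(nrow(t2$history), 2L)
  expect_error(train_model(model, list(), list(), cfg0), "empty")
})

test_that("model checkpoints round-trip through save/load", {
  model <- segmentation_model(tiny_config(), seed = 2)
  model$trained <- TRUE
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(model, f)
  back <- load_model(f)
  expect_identical(back$params, model$params)
  expect_identical(back$config, model$config)
  cl <- tiny_cloud(seed = 3)
  expect_identical(predict(back, cl)$labels, predict(model, cl)$labels)
})

test_that("prediction is invariant to permutation and translation", {
  cl <- tiny_cloud(seed = 11)
  model <- segmentation_model(tiny_config(), seed = 3)
  expect_error(predict(model, cl), "untrained")
  model$trained <- TRUE  # deterministic random-weight scorer
  base <- predict(model, cl)
  expect_equal(rowSums(base$scores), rep(1, n_points(cl)))
  expect_equal(max.col(base$scores) - 1L, base$labels)
  perm <- withr::with_seed(5, sample(n_points(cl)))
  ppred <- predict(model, cl[perm])
  expect_equal(ppred$labels, base$labels[perm])
  moved <- cl
  moved$coords <- sweep(cl$coords, 2, c(1000, -500, 250), `+`)
  expect_equal(predict(model, moved)$labels, base$labels)
})
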