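# a deliberately tiny architecture used by several tests
tiny_config <- function(dropout = 0) {
  network_config(
    sa_layers = list(
      sa_layer_config(16, c(2, 4), c(4, 8), list(8, 8)),
      sa_layer_config(8, 6, 4, list(12)),
      sa_layer_config(1, Inf, NA, list(16))
    ),
    ip_layers = list(ip_layer_config(12), ip_layer_config(12),
                     ip_layer_config(8)),
    head_channels = 8, dropout = dropout
  )
}

tiny_cloud <- function(n = 60, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(3 * n), n, 3)
  nr <- matrix(rnorm(3 * n), n, 3)
  point_cloud(m * 3, normals = nr / sqrt(rowSums(nr^2)),
              labels = sample(0:1, n, TRUE))
}

test_that("inverse-distance interpolation reproduces the closed forms", {
  # equidistant supports -> arithmetic mean
  sup <- rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0))
  expect_equal(interpolate_features(c(0, 0, 0), sup, cbind(c(1, 2, 3)), 3)[1, 1], 2)
  # distances 1 and 2, features 0 and 3 -> (1*0 + 0.25*3) / 1.25 = 0.6
  sup2 <- rbind(c(1, 0, 0), c(2, 0, 0))
  expect_equal(interpolate_features(c(0, 0, 0), sup2, cbind(c(0, 3)), 2)[1, 1], 0.6)
  # coincident support -> exact feature
  expect_equal(interpolate_features(c(1, 0, 0), sup2, cbind(c(7, 3)), 2)[1, 1], 7)
  expect_error(interpolate_features(c(0, 0, 0), sup2, cbind(c(0, 3)), 5), "k_interp")
})

test_that("interpolation stays within the convex span of neighbor features", {
  set.seed(9)
  sup <- matrix(rnorm(60), 20, 3)
  f <- matrix(rnorm(40), 20, 2)
  q <- matrix(rnorm(30), 10, 3)
  out <- interpolate_features(q, sup, f, 3)
  nn <- tasselseg:::.knn_query_cpp(q, sup, 3L)
  for (i in 1:10) {
    fs <- f[nn$idx[i, ], , drop = FALSE]
    expect_true(all(out[i, ] >= apply(fs, 2, min) - 1e-12))
    expect_true(all(out[i, ] <= apply(fs, 2, max) + 1e-12))
  }
})

test_that("cross-entropy loss matches closed forms and is zero iff one-hot correct", {
  expect_equal(cross_entropy_loss(rbind(c(1, 0), c(0, 1)), c(0, 1)), 0)
  expect_equal(cross_entropy_loss(matrix(0.5, 4, 2), rep(0L, 4)), log(2))
  expect_equal(cross_entropy_loss(rbind(c(0.9, 0.1)), 0L), -log(0.9))
  expect_gt(cross_entropy_loss(rbind(c(0.9, 0.1)), 1L), 0)
  expect_error(cross_entropy_loss(rbind(c(0.9, 0.1)), 2L), "range")
})

test_that("segmentation metrics: perfect match, forced counts, and oracle", {
  m <- segmentation_metrics(c(0, 1, 1, 0), c(0, 1, 1, 0))
  expect_true(all(m$iou == 1 & m$accuracy == 1 & m$precision == 1 & m$recall == 1))
  # counts TP=3 FP=1 FN=1 TN=5 for class 1
  pred <- c(rep(1, 3), 1, 0, rep(0, 5))
  truth <- c(rep(1, 3), 0, 1, rep(0, 5))
  m1 <- segmentation_metrics(pred, truth)[2, ]
  expect_equal(m1$iou, 0.6)
  expect_equal(m1$accuracy, 0.8)
  expect_equal(m1$precision, 0.75)
  expect_equal(m1$recall, 0.75)
  # brute-force confusion oracle on random labels
  for (seed in 1:20) {
    set.seed(seed)
    p <- sample(0:1, 1000, TRUE)
    t <- sample(0:1, 1000, TRUE)
    m <- segmentation_metrics(p, t)
    for (r in 1:2) {
      cc <- oracle_confusion(p, t, m$class[r])
      expect_equal(unlist(m[r, c("tp", "fp", "fn", "tn")]), cc)
      expect_equal(m$iou[r], cc["tp"] / (cc["tp"] + cc["fp"] + cc["fn"]),
                   ignore_attr = TRUE)
    }
  }
  # absent class -> 0/0 ratios reported as 1
  ma <- segmentation_metrics(rep(0, 5), rep(0, 5))
  expect_equal(ma$iou[2], 1)
  expect_equal(ma$precision[2], 1)
  expect_error(segmentation_metrics(1:3, 1:4), "mismatch")
})

test_that("forward output is a simplex, deterministic, and duplicate-consistent", {
  cl <- tiny_cloud()
  model <- init_tipnet(tiny_config(), seed = 3)
  p1 <- tipnet_forward(model, cl)
  expect_equal(dim(p1), c(60L, 2L))
  expect_true(all(p1 >= 0))
  expect_equal(rowSums(p1), rep(1, 60), tolerance = 1e-9)
  # bitwise determinism
  expect_identical(p1, tipnet_forward(model, cl))
  # duplicated point gets an identical probability row
  cl2 <- cl
  cl2$coords <- rbind(cl$coords, cl$coords[5, ])
  cl2$normals <- rbind(cl$normals, cl$normals[5, ])
  cl2$labels <- c(cl$labels, cl$labels[5])
  p2 <- tipnet_forward(model, cl2)
  expect_equal(p2[61, ], p2[5, ], tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  cl <- tiny_cloud(50, seed = 11)
  cfg <- tiny_config()
  model <- init_tipnet(cfg, seed = 2)
  plan <- tasselseg:::build_plan(cfg, cl$coords)
  fwd <- tasselseg:::tipnet_forward_full(model, plan, cl$normals, NULL)
  g <- tasselseg:::tipnet_backward_full(model, plan, fwd, cl$labels, NULL)
  loss_at <- function(params) {
    m <- model
    m$params <- params
    f <- tasselseg:::tipnet_forward_full(m, plan, cl$normals, NULL)
    cross_entropy_loss(f$prob, cl$labels)
  }
  eps <- 1e-6
  checks <- list(
    list(\(p) p$sa[[1]][[2]][[1]]$W[4, 6], \(p, v) { p$sa[[1]][[2]][[1]]$W[4, 6] <- v; p },
         g$sa[[1]][[2]][[1]]$W[4, 6]),
    list(\(p) p$sa[[3]][[1]][[1]]$W[7, 3], \(p, v) { p$sa[[3]][[1]][[1]]$W[7, 3] <- v; p },
         g$sa[[3]][[1]][[1]]$W[7, 3]),
    list(\(p) p$ip[[2]][[1]]$b[5], \(p, v) { p$ip[[2]][[1]]$b[5] <- v; p },
         g$ip[[2]][[1]]$b[5]),
    list(\(p) p$head$W1[3, 2], \(p, v) { p$head$W1[3, 2] <- v; p }, g$head$W1[3, 2]),
    list(\(p) p$head$b2[1], \(p, v) { p$head$b2[1] <- v; p }, g$head$b2[1])
  )
  for (ch in checks) {
    p0 <- model$params
    num <- (loss_at(ch[[2]](p0, ch[[1]](p0) + eps)) -
              loss_at(ch[[2]](p0, ch[[1]](p0) - eps))) / (2 * eps)
    expect_equal(ch[[3]], num, tolerance = 1e-4)
  }
})

test_that("training follows the lr schedule, is seeded, and can stop early", {
  set.seed(1)
  clouds <- lapply(1:2, function(i) tiny_cloud(40, seed = i))
  model <- init_tipnet(tiny_config(), seed = 5)
  cfg <- train_config(batch_size = 2, epochs = 3, seed = 9)
  fit1 <- train_tipnet(model, clouds, config = cfg)
  fit2 <- train_tipnet(model, clouds, config = cfg)
  expect_identical(fit1$history, fit2$history)
  expect_equal(fit1$history$epoch, 0:2)
  # lr schedule: 0.001 until epoch 19, halved at 20, quartered at 40
  cfg2 <- train_config(epochs = 45, lr_halving_period = 20, lr0 = 0.001,
                       loss_threshold = 0)
  lr_at <- function(epoch) cfg2$lr0 * 0.5^(epoch %/% cfg2$lr_halving_period)
  expect_equal(lr_at(0), 0.001)
  expect_equal(lr_at(20), 5e-4)
  expect_equal(lr_at(40), 2.5e-4)
  expect_equal(fit1$history$lr, rep(0.001, 3))
  # early stop: absurdly high threshold stops after the first epoch
  fit3 <- train_tipnet(model, clouds,
                       config = train_config(epochs = 10, loss_threshold = 100))
  expect_equal(nrow(fit3$history), 1L)
  expect_error(train_tipnet(model, list()), "empty")
})

test_that("predict_tips ties break to class 0 and labels are binary", {
  cl <- tiny_cloud(45, seed = 6)
  model <- init_tipnet(tiny_config(), seed = 7)
  out <- predict_tips(model, cl)
  expect_true(all(out$labels %in% c(0L, 1L)))
  p <- attr(out, "tip_prob")
  expect_identical(out$labels, as.integer(p[, 2] > p[, 1])) # tie -> 0
})

test_that("checkpoints round-trip through save/load", {
  model <- init_tipnet(tiny_config(), seed = 1)
  f <- withr::local_tempfile(fileext = ".rds")
  save_tipnet(model, f)
  back <- load_tipnet(f)
  expect_identical(back$params, model$params)
  cl <- tiny_cloud(30, seed = 2)
  expect_identical(tipnet_forward(model, cl), tipnet_forward(back, cl))
})

test_that("config validation catches malformed architectures", {
  expect_error(sa_layer_config(0, 1, 4, list(8)), "n_centroids")
  expect_error(sa_layer_config(8, c(2, 1), c(4, 4), list(8, 8)), "increasing")
  expect_error(network_config(list(), list()), "exactly 3")
  expect_error(train_config(momentum = 1.5))
})
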