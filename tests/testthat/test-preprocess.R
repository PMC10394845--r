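test_that("HSV mask follows the hexcone convention on forced colors", {
  cl <- point_cloud(matrix(0, 3, 3),
                    colors = rbind(c(1, 0, 0),      # pure red: H = 0 < 15
                                   c(0, 1, 0),      # pure green: H = 60
                                   c(0.5, 0.5, 0.5))) # gray: S = 0 < 0.05
  expect_identical(hsv_foreground_mask(cl), c(FALSE, TRUE, FALSE))
  expect_error(hsv_foreground_mask(point_cloud(matrix(0, 1, 3))), "color")
  expect_error(hsv_range(100, 50), "ordered")
})

test_that("outlier filter: symmetric sets keep everything, far point is removed", {
  # regular tetrahedron: every point's neighbor statistics are exactly equal
  tet <- point_cloud(rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)))
  res <- statistical_outlier_filter(tet, outlier_filter_params(3, 0.5))
  expect_length(res$removed, 0)
  # on a bounded grid only boundary points (larger neighbor means) can go;
  # the interior is never removed
  grid <- point_cloud(as.matrix(expand.grid(1:5, 1:5, 1:5)))
  res <- statistical_outlier_filter(grid, outlier_filter_params(6, 0.5))
  interior <- which(apply(grid$coords, 1, function(p) all(p > 1 & p < 5)))
  expect_length(intersect(res$removed, interior), 0)

  set.seed(11)
  ball <- matrix(rnorm(300), 100, 3)
  ball <- ball / pmax(sqrt(rowSums(ball^2)), 1) # inside unit ball
  cl <- point_cloud(rbind(ball, c(50, 0, 0)))
  res <- statistical_outlier_filter(cl, outlier_filter_params(10, 0.5))
  expect_identical(res$removed, 101L)
  expect_error(statistical_outlier_filter(point_cloud(matrix(0, 3, 3) + diag(3)),
                                          outlier_filter_params(20, 0.5)),
               "smaller")
})

test_that("outlier filter matches the brute-force oracle across seeds", {
  for (seed in 1:25) {
    cl <- random_cloud(200, seed = seed)
    got <- statistical_outlier_filter(cl, outlier_filter_params(20, 0.5))
    expect_identical(got$removed, oracle_sor_removed(cl$coords, 20, 0.5),
                     info = paste("seed", seed))
  }
})

test_that("outlier filter is monotone in alpha and partitions the input", {
  cl <- random_cloud(150, seed = 3)
  prev <- Inf
  for (a in c(0, 0.25, 0.5, 1, 2)) {
    res <- statistical_outlier_filter(cl, outlier_filter_params(10, a))
    expect_lte(length(res$removed), prev)
    expect_equal(n_points(res$kept) + length(res$removed), 150L)
    prev <- length(res$removed)
  }
})

test_that("random downsampling is seeded, uniform, and channel-consistent", {
  cl <- point_cloud(cbind(1:10, 0, 0), labels = 1:10 * 10L)
  expect_equal(random_downsample(cl, 10, seed = 99)$coords, cl$coords)
  one <- random_downsample(cl, 1, seed = 5)
  expect_true(one$coords[1] %in% 1:10)
  expect_equal(one$labels, as.integer(one$coords[1] * 10))
  expect_identical(random_downsample(cl, 4, seed = 7)$coords,
                   random_downsample(cl, 4, seed = 7)$coords)
  expect_error(random_downsample(cl, 11), "target_n")
})

test_that("FPS reproduces forced examples and the greedy oracle", {
  line <- matrix(c(0, 1, 2, 10, rep(0, 8)), 4)
  expect_identical(farthest_point_sample(line, 2), c(1L, 4L))
  expect_identical(farthest_point_sample(line, 3), c(1L, 4L, 3L)) # min-dist 2 beats 1
  for (seed in 1:20) {
    cl <- random_cloud(50, seed = seed)
    expect_identical(farthest_point_sample(cl, 10),
                     as.integer(oracle_fps(cl$coords, 10)),
                     info = paste("seed", seed))
  }
})

test_that("FPS with target N is a permutation and coverage shrinks monotonically", {
  cl <- random_cloud(60, seed = 8)
  expect_setequal(farthest_point_sample(cl, 60), 1:60)
  sel <- farthest_point_sample(cl, 30)
  d <- as.matrix(dist(cl$coords))
  cover <- vapply(2:30, function(k)
    max(apply(d[-sel[1:k], sel[1:k], drop = FALSE], 1, min)), numeric(1))
  expect_true(all(diff(cover) <= 1e-12))
})

test_that("normal estimation: plane, sphere orientation, smooth surface", {
  set.seed(4)
  plane <- point_cloud(cbind(runif(80), runif(80), 0))
  n <- estimate_normals(plane, 8)$normals
  expect_equal(abs(n[, 3]), rep(1, 80), tolerance = 1e-9)
  expect_equal(sqrt(rowSums(n^2)), rep(1, 80), tolerance = 1e-9)

  sph <- matrix(rnorm(900), 300, 3)
  sph <- sph / sqrt(rowSums(sph^2))
  ns <- estimate_normals(point_cloud(sph), 10)$normals
  expect_true(all(rowSums(ns * sph) > 0)) # oriented away from centroid

  # analytic oracle: z = 0.1 (x^2 + y^2), normal ~ (-0.2x, -0.2y, 1)
  set.seed(5)
  xy <- matrix(runif(2 * 400, -1, 1), ncol = 2)
  surf <- cbind(xy, 0.1 * (xy[, 1]^2 + xy[, 2]^2))
  nest <- estimate_normals(point_cloud(surf), 12)$normals
  truth <- cbind(-0.2 * xy[, 1], -0.2 * xy[, 2], 1)
  truth <- truth / sqrt(rowSums(truth^2))
  ang <- acos(pmin(1, abs(rowSums(nest * truth)))) * 180 / pi
  expect_lt(stats::quantile(ang, 0.95), 15)
})

test_that("mean nearest-neighbor distance matches examples and the oracle", {
  expect_equal(mean_nn_distance(point_cloud(cbind(0:3, 0, 0))), 1)
  expect_equal(mean_nn_distance(point_cloud(rbind(c(0, 0, 0), c(0, 0, 5)))), 5)
  for (seed in 1:20) {
    cl <- random_cloud(100, seed = seed)
    expect_equal(mean_nn_distance(cl), oracle_mean_nn(cl$coords),
                 tolerance = 1e-12, info = paste("seed", seed))
  }
  expect_error(mean_nn_distance(point_cloud(matrix(0, 1, 3))), "2 points")
})
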