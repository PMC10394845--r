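test_that("generation is deterministic per seed", {
  a <- generate_tassel(small_spec(seed = 5))
  b <- generate_tassel(small_spec(seed = 5))
  expect_identical(a$cloud$coords, b$cloud$coords)
  expect_identical(a$truth$per_branch, b$truth$per_branch)
  c <- generate_tassel(small_spec(seed = 6))
  expect_false(identical(a$cloud$coords, c$cloud$coords))
})

test_that("pinned parameters yield exact analytic ground truth", {
  # one straight branch: curvature exactly 1, angle exactly as drawn
  sp <- tassel_spec(n_branches = 1, insertion_angle = 45, curvature_factor = 1,
                    points_per_cm = 15, radial_jitter_sd = 0, seed = 3)
  gt <- generate_tassel(sp)
  expect_equal(gt$truth$per_branch$curvature, 1, tolerance = 1e-9)
  expect_equal(gt$truth$per_branch$angle, 45, tolerance = 1e-9)
  # drawn curvature is realized by the Bezier arc/chord ratio
  sp2 <- tassel_spec(n_branches = 3, curvature_factor = 1.3,
                     points_per_cm = 15, radial_jitter_sd = 0, seed = 4)
  gt2 <- generate_tassel(sp2)
  expect_equal(gt2$truth$per_branch$curvature, rep(1.3, 3), tolerance = 1e-6)
})

test_that("ground-truth lengths agree with independent quadrature over the points", {
  sp <- tassel_spec(n_branches = 2, points_per_cm = 60, radial_jitter_sd = 0,
                    seed = 8)
  gt <- generate_tassel(sp)
  for (b in 0:1) {
    pts <- gt$cloud$coords[gt$cloud$instance == b, , drop = FALSE]
    # points are ordered along arc; their polyline length underestimates the
    # true arc length by at most one sample cell at each end
    poly <- sum(sqrt(rowSums(diff(pts)^2)))
    expect_equal(poly, gt$truth$per_branch$length[b + 1],
                 tolerance = 2 / 60 * 3)
  }
})

test_that("tip labels cover the distal segment; colors pass the default mask", {
  gt <- generate_tassel(small_spec(seed = 9))
  cl <- gt$cloud
  expect_true(all(hsv_foreground_mask(cl)))
  for (b in unique(cl$instance)) {
    sel <- cl$instance == b & cl$labels == 1L
    m <- cl$coords[sel, , drop = FALSE]
    diam <- sqrt(sum((apply(m, 2, max) - apply(m, 2, min))^2))
    expect_lt(diam, 5) # a tip is a compact <= tip_label_length segment
    expect_gt(sum(sel), 10)
  }
  # outliers carry a hue the mask rejects and id -1
  sp <- small_spec(seed = 9)
  sp$outlier_fraction <- 0.05
  gt2 <- generate_tassel(sp)
  out <- gt2$cloud$instance == -1L
  expect_equal(sum(out), round(0.05 * sum(!out)))
  expect_true(all(!hsv_foreground_mask(gt2$cloud)[out]))
})

test_that("spec validation rejects out-of-convention parameters", {
  expect_error(tassel_spec(tip_label_length = 2), "3-5")
  expect_error(tassel_spec(curvature_factor = c(0.8, 1.2)), ">= 1")
  expect_error(tassel_spec(n_branches = c(10, 5)), "ordered")
  expect_error(generate_tassel(tassel_spec(n_branches = 30)), "n_branches")
})

test_that("dataset generation writes reproducible files and manifests", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_dataset(3, small_spec(), d1, seed = 11)
  m2 <- generate_dataset(3, small_spec(), d2, seed = 11)
  expect_equal(list.files(d1, pattern = "ply$"), paste0("tassel_00", 1:3, ".ply"))
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  expect_identical(unname(tools::md5sum(file.path(d1, "tassel_001.ply"))),
                   unname(tools::md5sum(file.path(d2, "tassel_001.ply"))))
  man <- read.csv(file.path(d1, "manifest.csv"))
  expect_true(all(man$branch_count >= 6 & man$branch_count <= 10))
  # the files are loadable and labeled
  pc <- read_point_cloud(file.path(d1, "tassel_002.ply"))
  expect_true(all(pc$labels %in% 0:1))
  expect_true(sum(pc$labels) > 0)
})

test_that("resampling augmentation keeps labels and is identity at full size", {
  gt <- generate_tassel(small_spec(seed = 13))
  n <- n_points(gt$cloud)
  same <- resample_augment(gt$cloud, n, 1, seed = 2)[[1]]
  expect_identical(same$coords, gt$cloud$coords)
  copies <- resample_augment(gt$cloud, 1000, 3, seed = 2)
  expect_false(identical(copies[[1]]$coords, copies[[2]]$coords))
  # label proportions concentrate near the parent proportion
  p0 <- mean(gt$cloud$labels)
  props <- vapply(resample_augment(gt$cloud, 1000, 50, seed = 5),
                  function(cl) mean(cl$labels), numeric(1))
  expect_true(all(abs(props - p0) <= 0.05))
  expect_error(resample_augment(gt$cloud, n + 1, 1), "target_n")
})
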