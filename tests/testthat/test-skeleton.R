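# hand-built Y shape: trunk along +z, two arms from the junction
y_shape <- function(arm1 = 10, arm2 = 6, trunk = 4, step = 0.5) {
  zs <- seq(0, trunk, by = step)
  trunk_pts <- cbind(0, 0, zs)
  a1 <- seq(step, arm1, by = step)
  arm1_pts <- cbind(a1 / sqrt(2), 0, trunk + a1 / sqrt(2))
  a2 <- seq(step, arm2, by = step)
  arm2_pts <- cbind(-a2 / sqrt(2), 0, trunk + a2 / sqrt(2))
  rbind(trunk_pts, arm1_pts, arm2_pts)
}

test_that("growth points are the nearest remainder points", {
  line <- cbind(0, 0, 0:8)
  tipc <- point_cloud(cbind(0, 0, seq(9, 10, by = 0.25)))
  inst <- density_cluster(tipc, cluster_params(eps = 1, min_pts = 2,
                                               min_cluster_size = 2))
  gp <- initial_growth_points(point_cloud(line), inst)
  expect_equal(gp, 9L) # the z = 8 point
  # coincident tip point -> that remainder point, zero distance
  tipc2 <- point_cloud(rbind(c(0, 0, 8), c(0, 0, 8.2), c(0, 0, 8.4)))
  inst2 <- density_cluster(tipc2, cluster_params(eps = 1, min_pts = 2,
                                                 min_cluster_size = 2))
  expect_equal(initial_growth_points(point_cloud(line), inst2), 9L)
})

test_that("convex hull volume: cube, inscribed tetrahedron, degeneracies", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convex_hull_volume(cube), 1)
  expect_equal(convex_hull_volume(cube[c(1, 4, 6, 7), ]), 1 / 3)
  expect_equal(convex_hull_volume(cube * 2), 8) # scaling law
  expect_equal(convex_hull_volume(matrix(rnorm(9), 3)), 0) # K < 4
  expect_equal(convex_hull_volume(cbind(runif(30), runif(30), 1)), 0) # coplanar
  expect_equal(convex_hull_volume(cbind(1:20, 1:20, 1:20)), 0) # collinear
})

test_that("hull volume matches the Monte-Carlo oracle on random box clouds", {
  set.seed(10)
  pts <- cbind(runif(200, 0, 2), runif(200, 0, 3), runif(200, 0, 5))
  v <- convex_hull_volume(pts)
  mc <- oracle_mc_hull_volume(pts, n_samples = 1e6, seed = 2)
  expect_lt(abs(v - mc) / mc, 0.01)
  # and the exact R oracle agrees to machine precision
  expect_equal(v, oracle_hull_volume(pts), tolerance = 1e-9)
})

test_that("root selection maximizes the growth-point hull, with fallback", {
  # growth points at the top corners of a unit cube, candidates below on z
  gp_coords <- rbind(c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  cands <- cbind(0.5, 0.5, seq(0.5, -3, by = -0.5))
  all_pts <- rbind(gp_coords, cands)
  root <- select_root(point_cloud(all_pts), 1:4)
  expect_equal(root, nrow(all_pts)) # the bottom-most candidate
  # single growth point: hulls all degenerate -> farthest point wins
  line <- cbind(0, 0, 0:10)
  expect_equal(select_root(point_cloud(line), 11L), 1L)
  expect_error(select_root(point_cloud(line[1:2, ]), 1:2), "only growth points")
  # argmax equals exhaustive evaluation on a random tassel-like set
  gt <- generate_tassel(small_spec(seed = 31))
  sub <- subset_cloud(gt$cloud, sort(farthest_point_sample(gt$cloud, 150)))
  gps <- c(3L, 40L, 90L)
  got <- select_root(sub, gps)
  vols <- vapply(setdiff(1:150, gps), function(i)
    convex_hull_volume(rbind(sub$coords[i, ], sub$coords[gps, ])), numeric(1))
  expect_equal(got, setdiff(1:150, gps)[which.max(vols)])
})

test_that("spanning tree on a line is the parent chain with unit edges", {
  line <- point_cloud(cbind(0, 0, 0:9))
  tree <- build_spanning_tree(line, root = 1, radius = 1.5)
  expect_equal(tree$parent, c(0L, 1:9))
  expect_equal(tree$edge_length[-1], rep(1, 9))
  expect_equal(tree$dist, 0:9)
})

test_that("radius expansion bridges disconnected clusters; guard triggers", {
  pts <- point_cloud(rbind(cbind(0, 0, seq(0, 2, 0.5)),
                           cbind(0, 0, seq(12, 14, 0.5))))
  tree <- build_spanning_tree(pts, root = 1, radius = 1, radius_growth = 1.5)
  expect_true(all(is.finite(tree$dist)))
  expect_equal(sum(tree$parent == 0L), 1L) # exactly one sentinel
  expect_error(build_spanning_tree(pts, root = 1, radius = 1, radius_growth = 1),
               "disconnected")
})

test_that("tree is a spanning tree and matches the Dijkstra oracle on a Y", {
  pts <- y_shape()
  tree <- build_spanning_tree(point_cloud(pts), root = 1, radius = 0.9)
  n <- nrow(pts)
  expect_equal(sum(tree$parent == 0L), 1L)
  # all nodes reach root, acyclically
  for (i in seq_len(n)) {
    expect_true(is.finite(tree$dist[i]))
    path <- tasselseg:::walk_to_root(tree$parent, i)
    expect_equal(path[length(path)], 1L)
  }
  expect_equal(tree$dist, oracle_dijkstra(pts, 1, tree$radius),
               tolerance = 1e-12)
})

test_that("branch paths truncate at the junction and share suffixes", {
  pts <- y_shape(arm1 = 10, arm2 = 6, trunk = 4)
  n <- nrow(pts)
  tip1 <- n - 13L # a node on arm1 near its end
  # instances: two single-point tips at the arm ends (use direct indices)
  tree <- build_spanning_tree(point_cloud(pts), root = 1, radius = 0.9)
  gp <- c(which.max(pts[, 1]), which.min(pts[, 1])) # arm1 end, arm2 end
  br <- extract_branch_paths(tree, gp, stem_rule = "longest")
  # main stem = trunk + long arm (length 14 beats 10)
  expect_equal(br$main_stem, 1L)
  expect_equal(br$path_lengths[1], 14, tolerance = 1e-9)
  # short branch truncates at the junction node (trunk top)
  poly <- br$polylines[[1]]
  base <- poly[nrow(poly), ]
  expect_equal(base, c(0, 0, 4), tolerance = 1e-9)
  expect_equal(tasselseg:::polyline_length(poly), 6, tolerance = 1e-9)
  # suffix sharing: both full paths coincide from the junction to the root
  p1 <- br$paths[[1]]
  p2 <- br$paths[[2]]
  shared <- intersect(p1, p2)
  expect_true(all(tail(p1, length(shared)) == tail(p2, length(shared))))
  # tie-break: equal arms -> instance 1 wins
  pts_sym <- y_shape(arm1 = 6, arm2 = 6)
  tree2 <- build_spanning_tree(point_cloud(pts_sym), root = 1, radius = 0.9)
  gp2 <- c(which.max(pts_sym[, 1]), which.min(pts_sym[, 1]))
  br2 <- extract_branch_paths(tree2, gp2, stem_rule = "longest")
  expect_equal(br2$main_stem, 1L)
  # single growth point: its path is the stem, no branches
  br3 <- extract_branch_paths(tree, gp[1], stem_rule = "longest")
  expect_equal(length(br3$polylines), 0L)
})

test_that("branch path lengths equal Dijkstra distances (tree-path optimality)", {
  gt <- generate_tassel(small_spec(seed = 17))
  res <- run_pipeline(gt$cloud, pipeline_config(), "ground-truth-tips")
  tree <- res$tree
  for (k in seq_along(res$branches$paths)) {
    p <- res$branches$paths[[k]]
    plen <- tasselseg:::polyline_length(tree$node_coords[p, , drop = FALSE])
    expect_equal(plen, tree$dist[p[1]], tolerance = 1e-9)
  }
})

test_that("point fusion covers every point with valid ids and a stated tie-break", {
  # point 0.1 from branch A, far from the stem -> id A (= 0)
  stem <- cbind(0, 0, seq(0, 10, 0.5))
  branchA <- cbind(seq(0.5, 5, 0.5), 0, 5)
  branches <- structure(list(
    stem_polyline = stem[rev(seq_len(nrow(stem))), ],
    polylines = list(branchA[rev(seq_len(nrow(branchA))), ])
  ), class = "branch_set")
  q <- point_cloud(rbind(c(3, 0.1, 5), c(0, 0, 2), c(0.25, 0, 5)))
  ids <- assign_points_to_branches(q, branches)
  expect_equal(ids[1], 0L)
  expect_equal(ids[2], -2L)
  expect_equal(ids[3], -2L) # exact tie between stem and branch -> stem wins
  expect_true(all(ids %in% c(-2L, 0L)))
})

test_that("end-to-end fusion matches generator membership on a noiseless tassel", {
  gt <- generate_tassel(small_spec(seed = 12))
  res <- run_pipeline(gt$cloud, pipeline_config(), "ground-truth-tips")
  # map measured branch ids to generator ids via tip instances
  tips <- subset_cloud(res$cloud, res$tip_idx)
  gid_of_branch <- vapply(seq_along(res$branches$polylines), function(b) {
    k <- res$branches$branch_instance[b]
    mem <- tips$instance[res$instances$instance_ids == (k - 1L)]
    as.integer(names(which.max(table(mem))))
  }, integer(1))
  truth <- res$cloud$instance # generator ids survive the subsetting
  mapped <- rep(-2L, length(res$membership))
  sel <- res$membership >= 0L
  mapped[sel] <- gid_of_branch[res$membership[sel] + 1L]
  agree <- mean(mapped == truth)
  expect_gte(agree, 0.98)
})
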