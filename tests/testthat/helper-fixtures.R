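# shared fixture builders (everything is generated in code; no data files)

# a small, fast tassel: lower density, fewer branches
small_spec <- function(seed = 1, ...) {
  tassel_spec(n_branches = c(6, 10), points_per_cm = 15,
              radial_jitter_sd = 0, outlier_fraction = 0, seed = seed, ...)
}

# the stated-world spec for recovery runs (noiseless = no jitter/outliers)
recovery_spec <- function(seed) {
  tassel_spec(n_branches = c(6, 16), branch_length = c(10, 30),
              insertion_angle = c(20, 60), curvature_factor = c(1, 1.4),
              radial_jitter_sd = 0, outlier_fraction = 0, seed = seed)
}

random_cloud <- function(n, seed = 1, scale = 1) {
  set.seed(seed)
  point_cloud(matrix(stats::rnorm(3 * n, sd = scale), n, 3))
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  qr_q
}

# match measured branches to generator branches through the tip instances:
# each measured branch's instance takes the majority true branch id of its
# member points
match_branches <- function(res, gt) {
  tips <- subset_cloud(res$cloud, res$tip_idx)
  out <- data.frame()
  for (b in seq_along(res$branches$polylines)) {
    k <- res$branches$branch_instance[b]
    mem <- tips$instance[res$instances$instance_ids == (k - 1L)]
    gid <- as.integer(names(which.max(table(mem))))
    if (gid < 0) next # stem or outlier majority
    g <- gt$truth$per_branch[gt$truth$per_branch$branch == gid, ]
    out <- rbind(out, data.frame(
      gid = gid,
      length = res$traits$branch_lengths[b], true_length = g$length,
      angle = res$traits$branch_angles[b], true_angle = g$angle,
      curvature = res$traits$branch_curvatures[b], true_curvature = g$curvature))
  }
  out
}
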