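#' HSV range for foreground masking
#'
#' Hue is expressed on the 0-180 half-degree scale common in imaging
#' pipelines (degrees / 2), saturation and value in `[0, 1]`. The defaults
#' keep the green-yellow tassel hues and drop the red/neutral background
#' (cloth, calibration markers, reflections).
#'
#' @param h_min,h_max hue bounds on the 0-180 scale.
#' @param s_min,s_max saturation bounds in `[0, 1]`.
#' @param v_min,v_max value bounds in `[0, 1]`.
#' @return an `hsv_range` list.
#' @export
hsv_range <- function(h_min = 15, h_max = 180, s_min = 0.05, s_max = 1,
                      v_min = 0, v_max = 1) {
  r <- list(h_min = h_min, h_max = h_max, s_min = s_min, s_max = s_max,
            v_min = v_min, v_max = v_max)
  if (h_min > h_max || s_min > s_max || v_min > v_max)
    stop("hsv_range bounds must be ordered")
  if (h_min < 0 || h_max > 180) stop("hue bounds must lie in [0, 180]")
  structure(r, class = "hsv_range")
}

#' Foreground mask from vertex colors in HSV space
#'
#' Converts per-vertex RGB to HSV with the standard hexcone model and keeps
#' points whose (H, S, V) triple falls inside all three intervals of
#' `range`. Hue is reported on the 0-180 (degrees / 2) scale.
#'
#' @param cloud a [point_cloud()] with colors.
#' @param range an [hsv_range()].
#' @return logical mask over points (`TRUE` = foreground).
#' @export
hsv_foreground_mask <- function(cloud, range = hsv_range()) {
  if (is.null(cloud$colors)) stop("cloud has no color channel")
  hsv <- grDevices::rgb2hsv(t(cloud$colors), maxColorValue = 1)
  h <- hsv[1, ] * 180 # rgb2hsv returns h in [0,1] = fraction of 360 deg
  s <- hsv[2, ]
  v <- hsv[3, ]
  h >= range$h_min & h <= range$h_max &
    s >= range$s_min & s <= range$s_max &
    v >= range$v_min & v <= range$v_max
}

#' Parameters of the statistical outlier filter
#'
#' @param n_neighbors number of nearest neighbors per query point (default
#'   20, the setting under which the filter's behavior was characterized).
#' @param alpha standard-deviation multiplier; 0.5 gives a relatively smooth
#'   edge while preserving most of the surface.
#' @return an `outlier_filter_params` list.
#' @export
outlier_filter_params <- function(n_neighbors = 20, alpha = 0.5) {
  if (n_neighbors < 2) stop("n_neighbors must be >= 2")
  if (alpha < 0) stop("alpha must be >= 0")
  structure(list(n_neighbors = as.integer(n_neighbors), alpha = alpha),
            class = "outlier_filter_params")
}

#' Statistical outlier removal
#'
#' Classical two-pass scheme: each point's mean distance to its
#' `n_neighbors` nearest neighbors is computed, then a point is removed iff
#' its mean exceeds the global mean of those means plus `alpha` times their
#' (sample) standard deviation. Larger `alpha` keeps more points.
#'
#' @param cloud a [point_cloud()].
#' @param params an [outlier_filter_params()].
#' @return list with `kept` (the filtered [point_cloud()], original order
#'   preserved), `removed` (integer indices into the input) and
#'   `mean_dist` (per-point mean neighbor distance).
#' @export
statistical_outlier_filter <- function(cloud, params = outlier_filter_params()) {
  n <- n_points(cloud)
  if (params$n_neighbors >= n)
    stop("n_neighbors must be smaller than the number of points")
  nn <- .knn_self_cpp(cloud$coords, params$n_neighbors)
  mu <- rowMeans(nn$dist)
  thr <- mean(mu) + params$alpha * stats::sd(mu)
  removed <- which(mu > thr)
  kept <- if (length(removed)) subset_cloud(cloud, -removed) else cloud
  list(kept = kept, removed = removed, mean_dist = mu)
}

#' Seeded uniform random downsampling
#'
#' The quick first-stage downsampling step: draws `target_n` distinct points
#' uniformly without replacement. Different seeds give different index
#' sequences, which is also the dataset-enhancement mechanism.
#'
#' @param cloud a [point_cloud()].
#' @param target_n number of points to keep (`1 <= target_n <= N`).
#' @param seed integer seed; fixed seed gives identical output.
#' @return the downsampled [point_cloud()].
#' @export
random_downsample <- function(cloud, target_n, seed = 1L) {
  n <- n_points(cloud)
  if (target_n < 1 || target_n > n)
    stop("target_n must lie in [1, N]")
  idx <- withr_seed(seed, sample.int(n, target_n))
  subset_cloud(cloud, sort(idx))
}

# evaluate expr under a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Farthest-point (maximin) sampling
#'
#' Greedy coverage-preserving subsampling: starting from `start_index`, each
#' subsequent pick maximizes the minimum distance to the already-selected
#' set; ties break to the lowest index.
#'
#' @param cloud a [point_cloud()] (or an `N x 3` matrix).
#' @param target_n number of indices to select.
#' @param start_index index of the first selected point (default 1).
#' @return integer vector of `target_n` distinct indices in selection order.
#' @export
farthest_point_sample <- function(cloud, target_n, start_index = 1L) {
  coords <- if (inherits(cloud, "point_cloud")) cloud$coords else as_coord_matrix(cloud)
  if (target_n < 1 || target_n > nrow(coords))
    stop("target_n must lie in [1, N]")
  as.integer(.fps_cpp(coords, as.integer(target_n), as.integer(start_index)))
}

#' Estimate per-point unit normals
#'
#' The normal of each point is the eigenvector of the smallest eigenvalue of
#' its k-nearest-neighbor covariance, oriented away from the cloud centroid.
#' Degenerate neighborhoods (rank < 2) fall back to +z with a warning.
#'
#' @param cloud a [point_cloud()].
#' @param k neighbor count (`3 <= k < N`).
#' @return the input [point_cloud()] with a `normals` channel.
#' @export
estimate_normals <- function(cloud, k = 16L) {
  n <- n_points(cloud)
  if (k < 3 || k >= n) stop("k must satisfy 3 <= k < N")
  nn <- .knn_self_cpp(cloud$coords, as.integer(k))
  centroid <- colMeans(cloud$coords)
  normals <- matrix(0, n, 3)
  degenerate <- FALSE
  for (i in seq_len(n)) {
    nb <- cloud$coords[nn$idx[i, ], , drop = FALSE]
    cv <- stats::cov(nb)
    ev <- eigen(cv, symmetric = TRUE)
    if (ev$values[2] <= 1e-12 * max(ev$values[1], 1e-300)) {
      normals[i, ] <- c(0, 0, 1)
      degenerate <- TRUE
      next
    }
    v <- ev$vectors[, 3]
    if (sum(v * (cloud$coords[i, ] - centroid)) < 0) v <- -v
    normals[i, ] <- v / sqrt(sum(v^2))
  }
  if (degenerate)
    warning("zero-variance neighborhood(s): normal set to +z")
  cloud$normals <- normals
  cloud
}

#' Mean nearest-neighbor distance
#'
#' The scale proxy used for adaptive radii: the mean over points of the
#' distance to each point's single nearest neighbor.
#'
#' @param cloud a [point_cloud()] or `N x 3` matrix with at least 2 points.
#' @return mean nearest-neighbor distance (cm).
#' @export
mean_nn_distance <- function(cloud) {
  coords <- if (inherits(cloud, "point_cloud")) cloud$coords else as_coord_matrix(cloud)
  if (nrow(coords) < 2) stop("need at least 2 points")
  nn <- .knn_self_cpp(coords, 1L)
  mean(nn$dist)
}
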