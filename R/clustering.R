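#' Density-clustering parameters
#'
#' @param eps search radius in cm, or `"auto"` for 3 x the mean
#'   nearest-neighbor distance of the clustered points (the adaptive radius
#'   appropriate after farthest-point downsampling, which homogenizes
#'   density).
#' @param min_pts neighborhood density threshold (core point = at least
#'   `min_pts` points within `eps`, itself included). Default 5.
#' @param min_cluster_size smallest accepted instance; smaller clusters are
#'   relabeled as noise. Default 10, which rejects stray mislabeled boundary
#'   points at the ~4000-point working resolution.
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(eps = "auto", min_pts = 5L, min_cluster_size = 10L) {
  if (min_pts < 1) stop("min_pts must be >= 1")
  if (min_cluster_size < 1) stop("min_cluster_size must be >= 1")
  if (!identical(eps, "auto") && (!is.numeric(eps) || eps <= 0))
    stop("eps must be a positive number or \"auto\"")
  structure(list(eps = eps, min_pts = as.integer(min_pts),
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "cluster_params")
}

#' Cluster branch-tip points into instances (DBSCAN)
#'
#' Standard DBSCAN semantics with a pinned tie-break: seeds are scanned in
#' ascending index order and cluster expansion is breadth-first, so a border
#' point joins the first core point that reaches it. Clusters smaller than
#' `min_cluster_size` are relabeled noise (-1); survivors are renumbered
#' 0, 1, ... by descending size (ties: first-seen first).
#'
#' @param tip_points a [point_cloud()] of network-labeled tip points.
#' @param params a [cluster_params()].
#' @return a `tip_instance_set`: list with `instance_ids` (per-point, -1 =
#'   noise), `n_instances`, `centroids` (`n_instances x 3`), `eps` (the
#'   radius actually used) and `sizes`.
#' @export
density_cluster <- function(tip_points, params = cluster_params()) {
  coords <- if (inherits(tip_points, "point_cloud")) tip_points$coords
    else as_coord_matrix(tip_points)
  n <- nrow(coords)
  if (n < 1) stop("empty input")
  eps <- params$eps
  if (identical(eps, "auto")) {
    # d_mean over a 20-point neighborhood (the same neighborhood statistic
    # the outlier filter uses), not the single-NN mean: after farthest-point
    # downsampling the single-NN distance underestimates the largest
    # within-organ gaps by up to 2x and fragments tip clusters
    eps <- if (n >= 2) {
      k <- min(20L, n - 1L)
      3 * mean(.knn_self_cpp(coords, k)$dist)
    } else 1
  }
  nb <- .radius_neighbors_cpp(coords, eps)
  core <- vapply(nb, length, 1L) >= params$min_pts
  ids <- rep(-1L, n)
  cluster <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || ids[i] != -1L) next
    ids[i] <- cluster
    queue <- i
    head <- 1L
    while (head <= length(queue)) {
      u <- queue[head]
      head <- head + 1L
      for (v in nb[[u]]) {
        if (ids[v] == -1L) {
          ids[v] <- cluster
          if (core[v]) queue <- c(queue, v)
        }
      }
    }
    cluster <- cluster + 1L
  }
  # reject small clusters, renumber survivors by descending size
  if (cluster > 0L) {
    sizes <- tabulate(ids + 1L, nbins = cluster)
    keep <- which(sizes >= params$min_cluster_size)
    ord <- keep[order(-sizes[keep], keep)]
    remap <- rep(-1L, cluster)
    remap[ord] <- seq_along(ord) - 1L
    pos <- ids >= 0L
    ids[pos] <- remap[ids[pos] + 1L]
    n_instances <- length(ord)
  } else {
    n_instances <- 0L
  }
  centroids <- if (n_instances > 0)
    t(vapply(seq_len(n_instances) - 1L, function(k)
      colMeans(coords[ids == k, , drop = FALSE]), numeric(3)))
    else matrix(numeric(0), 0, 3)
  sizes <- if (n_instances > 0) tabulate(ids + 1L, nbins = n_instances) else integer(0)
  structure(list(instance_ids = as.integer(ids),
                 n_instances = as.integer(n_instances),
                 centroids = centroids, eps = eps, sizes = sizes,
                 coords = coords),
            class = "tip_instance_set")
}

#' Number of accepted instances
#'
#' The branch-count estimator at the clustering stage: the number of
#' accepted tip clusters.
#'
#' @param instances a `tip_instance_set` from [density_cluster()].
#' @return integer count.
#' @export
branch_count <- function(instances) {
  if (is.null(instances)) return(0L)
  as.integer(instances$n_instances)
}
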