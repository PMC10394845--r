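#' Nearest-remainder growth point per tip instance
#'
#' For each tip instance, the skeleton seed is the remainder point closest
#' to any member of that instance (ties to the lowest remainder index).
#'
#' @param remainder a [point_cloud()] (or matrix) of non-tip points, e.g.
#'   the downsampled skeleton nodes.
#' @param instances a `tip_instance_set` from [density_cluster()] (which
#'   retains the clustered coordinates).
#' @return integer vector: one remainder index per instance.
#' @export
initial_growth_points <- function(remainder, instances) {
  coords <- if (inherits(remainder, "point_cloud")) remainder$coords
    else as_coord_matrix(remainder)
  if (nrow(coords) < 1) stop("empty remainder")
  if (instances$n_instances < 1) stop("no tip instances")
  vapply(seq_len(instances$n_instances) - 1L, function(k) {
    members <- instances$coords[instances$instance_ids == k, , drop = FALSE]
    nn <- .knn_query_cpp(members, coords, 1L)
    d <- nn$dist[, 1]
    cand <- nn$idx[d <= min(d) + 0, 1]
    as.integer(min(cand))
  }, integer(1))
}

#' Volume of the 3-D convex hull
#'
#' Degenerate inputs (fewer than 4 points, collinear or coplanar sets)
#' return 0.
#'
#' @param points `K x 3` coordinate matrix (or a [point_cloud()]).
#' @return hull volume in cm^3.
#' @export
convex_hull_volume <- function(points) {
  coords <- if (inherits(points, "point_cloud")) points$coords
    else as_coord_matrix(points)
  .hull_volume_cpp(coords)
}

#' Select the skeleton root node
#'
#' Every remainder point (growth points excluded) is evaluated as the apex
#' of the convex hull formed with all growth points; the candidate with the
#' largest hull volume — the point "most opposite" the branch tops, i.e. the
#' tassel base — wins. When every candidate yields volume 0 (fewer than 3
#' growth points, or degenerate geometry) the candidate maximizing the sum
#' of distances to the growth points is returned. Ties break to the lowest
#' index.
#'
#' @param remainder a [point_cloud()] or matrix of candidate points.
#' @param growth_points integer indices of growth points within `remainder`.
#' @return the root index.
#' @export
select_root <- function(remainder, growth_points) {
  coords <- if (inherits(remainder, "point_cloud")) remainder$coords
    else as_coord_matrix(remainder)
  if (length(growth_points) < 1) stop("need at least one growth point")
  cand <- setdiff(seq_len(nrow(coords)), growth_points)
  if (!length(cand)) stop("remainder contains only growth points")
  gp <- coords[growth_points, , drop = FALSE]
  vols <- vapply(cand, function(i)
    .hull_volume_cpp(rbind(coords[i, ], gp)), numeric(1))
  if (max(vols) > 0) return(cand[which.max(vols)])
  dsum <- vapply(cand, function(i)
    sum(sqrt(colSums((t(gp) - coords[i, ])^2))), numeric(1))
  cand[which.max(dsum)]
}

# Dijkstra on the radius graph with per-node radius expansion: unreachable
# nodes get their radius multiplied by `growth` until the graph is connected
# (at most `max_expand` rounds).
dijkstra_expand <- function(coords, root, radius, growth = 1.5,
                            max_expand = 20L) {
  rad <- rep(radius, nrow(coords))
  expansions <- 0L
  repeat {
    res <- .dijkstra_radius_cpp(coords, as.integer(root), rad)
    unreached <- !is.finite(res$dist)
    if (!any(unreached)) return(c(res, list(radius = rad)))
    if (growth <= 1)
      stop("radius graph disconnected and radius_growth <= 1")
    expansions <- expansions + 1L
    if (expansions > max_expand)
      stop("radius graph still disconnected after ", max_expand, " expansions")
    rad[unreached] <- rad[unreached] * growth
  }
}

#' Build the skeleton spanning tree
#'
#' Single-source shortest-path (Dijkstra) tree over the radius graph: points
#' within `radius` of each other are joined by an edge weighted by Euclidean
#' distance, and each node's parent is its predecessor on the minimal path
#' from the root. If parts of the cloud are unreachable, their search radius
#' is multiplied by `radius_growth` until the tree spans all nodes (the
#' multi-layer neighborhood that absorbs unevenly sampled clouds).
#'
#' @param remainder a [point_cloud()] or matrix of skeleton node positions
#'   (typically the FPS-downsampled non-tip cloud).
#' @param root root node index.
#' @param radius neighbor radius in cm, or `"auto"` for 3 x the mean
#'   nearest-neighbor distance of the nodes.
#' @param radius_growth expansion factor applied to unreachable nodes.
#' @return a `skeleton_tree`: list with `node_coords`, `parent` (0 for the
#'   root — the termination sentinel), `root`, `edge_length`, `dist`
#'   (geodesic distance to root) and `radius`.
#' @export
build_spanning_tree <- function(remainder, root, radius = "auto",
                                radius_growth = 1.5) {
  coords <- if (inherits(remainder, "point_cloud")) remainder$coords
    else as_coord_matrix(remainder)
  if (root < 1 || root > nrow(coords)) stop("root out of range")
  if (identical(radius, "auto")) radius <- 3 * mean_nn_distance(coords)
  res <- dijkstra_expand(coords, root, radius, radius_growth)
  parent <- res$parent
  edge_length <- ifelse(parent > 0,
                        sqrt(rowSums((coords - coords[pmax(parent, 1), ])^2)),
                        0)
  structure(list(node_coords = coords, parent = as.integer(parent),
                 root = as.integer(root), edge_length = edge_length,
                 dist = res$dist, radius = res$radius),
            class = "skeleton_tree")
}

walk_to_root <- function(parent, from) {
  path <- integer(0)
  v <- from
  steps <- 0L
  while (v != 0L) {
    path <- c(path, v)
    v <- parent[v]
    steps <- steps + 1L
    if (steps > length(parent)) stop("parent pointers contain a cycle")
  }
  path
}

polyline_length <- function(coords) {
  if (nrow(coords) < 2) return(0)
  sum(sqrt(rowSums(diff(coords)^2)))
}

# maximum turning angle (degrees) along a polyline, with directions averaged
# over +-window cm of arc around each vertex
max_turn_angle <- function(coords, window = 2) {
  n <- nrow(coords)
  if (n < 3) return(0)
  seglen <- sqrt(rowSums(diff(coords)^2))
  cum <- c(0, cumsum(seglen))
  worst <- 0
  for (i in 2:(n - 1)) {
    jb <- max(which(cum <= cum[i] - window), 1)
    ja <- min(which(cum >= cum[i] + window), n)
    if (ja == i || jb == i) { # endpoints too close; use immediate neighbors
      jb <- min(jb, i - 1)
      ja <- max(ja, i + 1)
    }
    u <- coords[i, ] - coords[jb, ]
    v <- coords[ja, ] - coords[i, ]
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) next
    ang <- acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
    if (ang > worst) worst <- ang
  }
  worst
}

# geodesic polyline through a tip instance: from the growth point through the
# instance's points to its farthest (distal) member; returns a coordinate
# matrix ordered distal tip -> growth point, or NULL for tiny instances
tip_extension_polyline <- function(growth_coord, member_coords) {
  pts <- rbind(growth_coord, member_coords)
  if (nrow(member_coords) < 1) return(NULL)
  if (nrow(pts) == 2)
    return(matrix(member_coords, ncol = 3))
  r0 <- 3 * mean_nn_distance(pts)
  res <- dijkstra_expand(pts, 1L, r0)
  distal <- which.max(res$dist)
  path <- walk_to_root(res$parent, distal)
  pts[path[-length(path)], , drop = FALSE] # drop the growth point itself
}

#' Extract per-branch skeleton paths and identify the main stem
#'
#' Each tip instance's skeleton path is the parent-following node sequence
#' from its growth point to the root. The main stem is then identified and
#' every other path is truncated at its branch base — the first node
#' (walking from the tip) shared with the main-stem path. When the tip
#' instances are supplied, each path is extended from its growth point
#' through the instance to the distal end of the branch, so that branch
#' polylines span the full organ (the trait definitions measure between the
#' branch's endpoints).
#'
#' Two main-stem rules are available. `"longest"` takes the path of maximal
#' polyline length. `"straightest"` (default) takes the longest path whose
#' maximum windowed turning angle stays below `turn_threshold`: lateral
#' branches always turn by at least their insertion angle where they leave
#' the stem, while the spindle runs straight through the branch zone, so
#' this rule still identifies the spindle when a high-attached long branch
#' out-measures it. If no path qualifies, the longest rule is the fallback.
#'
#' @param tree a [build_spanning_tree()] result.
#' @param growth_points per-instance node indices from
#'   [initial_growth_points()].
#' @param instances optional `tip_instance_set`; enables tip extension.
#' @param stem_rule `"straightest"` or `"longest"`.
#' @param turn_window arc window (cm) for turning-angle estimation.
#' @param turn_threshold maximum turning angle (degrees) for a path to count
#'   as straight.
#' @return a `branch_set`: list with `paths` (per-instance node index
#'   vectors, tip to root), `main_stem` (instance index of the stem path),
#'   `branch_base` (per-instance node index where the path meets the stem),
#'   `polylines` (per-branch coordinate matrices, distal tip to branch
#'   base, stem excluded), `branch_instance` (tip-instance index of each
#'   polyline), `stem_polyline` (coordinates, top to root), `stem_base_row`
#'   (row of each branch's base within `stem_polyline`), and `growth_points`.
#' @export
extract_branch_paths <- function(tree, growth_points, instances = NULL,
                                 stem_rule = c("straightest", "longest"),
                                 turn_window = 2, turn_threshold = 15) {
  stem_rule <- match.arg(stem_rule)
  n_inst <- length(growth_points)
  if (n_inst < 1) stop("need at least one growth point")
  paths <- vector("list", n_inst)
  for (k in seq_len(n_inst)) {
    gp <- growth_points[k]
    if (!is.finite(tree$dist[gp]))
      stop("growth point of instance ", k - 1L, " unreachable from root")
    paths[[k]] <- walk_to_root(tree$parent, gp)
  }
  plens <- vapply(paths, function(p)
    polyline_length(tree$node_coords[p, , drop = FALSE]), numeric(1))

  main <- NULL
  if (stem_rule == "straightest") {
    turns <- vapply(paths, function(p)
      max_turn_angle(tree$node_coords[p, , drop = FALSE], turn_window),
      numeric(1))
    straight <- which(turns <= turn_threshold)
    if (length(straight)) main <- straight[which.max(plens[straight])]
  }
  if (is.null(main)) main <- which.max(plens) # longest rule / fallback

  # tip extensions (coordinates beyond the growth point, distal first)
  tips <- vector("list", n_inst)
  if (!is.null(instances)) {
    for (k in seq_len(n_inst)) {
      members <- instances$coords[instances$instance_ids == (k - 1L), ,
                                  drop = FALSE]
      tips[[k]] <- tip_extension_polyline(
        tree$node_coords[growth_points[k], ], members)
    }
  }

  stem_nodes <- paths[[main]]
  stem_polyline <- rbind(tips[[main]],
                         tree$node_coords[stem_nodes, , drop = FALSE])
  n_tip_stem <- if (is.null(tips[[main]])) 0L else nrow(tips[[main]])
  stem_row_of_node <- integer(length(tree$parent))
  stem_row_of_node[stem_nodes] <- seq_along(stem_nodes) + n_tip_stem

  branch_base <- integer(n_inst)
  polylines <- list()
  branch_instance <- integer(0)
  stem_base_row <- integer(0)
  stem_set <- rep(FALSE, length(tree$parent))
  stem_set[stem_nodes] <- TRUE
  for (k in seq_len(n_inst)) {
    on_stem <- stem_set[paths[[k]]]
    base_pos <- if (any(on_stem)) which(on_stem)[1] else length(paths[[k]])
    branch_base[k] <- paths[[k]][base_pos]
    if (k == main) next
    seg <- paths[[k]][seq_len(base_pos)]
    poly <- rbind(tips[[k]], tree$node_coords[seg, , drop = FALSE])
    polylines[[length(polylines) + 1L]] <- poly
    branch_instance <- c(branch_instance, k)
    stem_base_row <- c(stem_base_row, stem_row_of_node[branch_base[k]])
  }

  structure(list(paths = paths, path_lengths = plens,
                 main_stem = as.integer(main),
                 branch_base = branch_base, polylines = polylines,
                 branch_instance = branch_instance,
                 stem_polyline = stem_polyline,
                 stem_base_row = stem_base_row,
                 growth_points = as.integer(growth_points)),
            class = "branch_set")
}

#' Fuse all original points onto the nearest branch
#'
#' Every point of the full-resolution cloud is assigned to the skeleton
#' polyline (main stem or branch) with minimal point-to-polyline distance
#' (distance to the nearest segment, not the nearest node). Ties resolve to
#' the main stem first, then the lower branch id. The main stem carries
#' id -2; branches are numbered 0, 1, ... in `branches$polylines` order.
#'
#' @param full_cloud a [point_cloud()] (or matrix).
#' @param branches a `branch_set` from [extract_branch_paths()].
#' @return integer vector of per-point branch ids.
#' @export
assign_points_to_branches <- function(full_cloud, branches) {
  coords <- if (inherits(full_cloud, "point_cloud")) full_cloud$coords
    else as_coord_matrix(full_cloud)
  if (length(branches$polylines) + 1L < 1) stop("no branch polylines")
  best <- .polyline_dist_cpp(coords, branches$stem_polyline)
  ids <- rep(-2L, nrow(coords))
  for (b in seq_along(branches$polylines)) {
    d <- .polyline_dist_cpp(coords, branches$polylines[[b]])
    upd <- d < best # strict: earlier (stem, then lower id) wins ties
    ids[upd] <- b - 1L
    best[upd] <- d[upd]
  }
  ids
}
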