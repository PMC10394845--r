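#' Branch length along the skeleton polyline
#'
#' Sum of consecutive-node Euclidean distances from the branch's distal tip
#' node to its base.
#'
#' @param path ordered node positions (`K x 3`, `K >= 2`).
#' @return length in cm.
#' @export
branch_length <- function(path) {
  path <- as_coord_matrix(path)
  if (nrow(path) < 2) stop("a branch path needs at least 2 nodes")
  polyline_length(path)
}

#' Branch curvature (arc length over chord)
#'
#' Ratio of the polyline length to the straight-line distance between the
#' branch's endpoints; 1 for a straight branch, larger when bent.
#'
#' @param path ordered node positions (`K x 3`).
#' @return dimensionless ratio >= 1.
#' @export
branch_curvature <- function(path) {
  path <- as_coord_matrix(path)
  if (nrow(path) < 2) stop("a branch path needs at least 2 nodes")
  chord <- sqrt(sum((path[1, ] - path[nrow(path), ])^2))
  if (chord == 0) stop("coincident branch endpoints")
  branch_length(path) / chord
}

#' Branch insertion angle against the local main stem
#'
#' The angle between the branch direction near its base (the secant from the
#' base to the node `arc_fraction` of the branch's arc length up from the
#' base) and the local main-stem direction at the attachment (the secant
#' from the base toward the tassel top over `stem_window` cm of stem arc),
#' in degrees. A near-base secant is used rather than the base-to-tip chord
#' so that drooping branches do not invert the measured angle.
#'
#' @param branch_path branch polyline, ordered distal tip to base
#'   (`K x 3`).
#' @param main_stem_path main-stem polyline, ordered top to root.
#' @param base_row row index of the branch base within `main_stem_path`; by
#'   default the stem row nearest the branch's base node.
#' @param arc_fraction fraction of branch arc length defining the branch
#'   direction secant (default 0.25).
#' @param stem_window stem arc length (cm) defining the local stem direction;
#'   `"auto"` (default) uses 5 x the median stem node spacing, which makes
#'   the angle scale-invariant while still averaging over several nodes.
#' @return insertion angle in degrees, in `[0, 180)`.
#' @export
branch_angle <- function(branch_path, main_stem_path, base_row = NULL,
                         arc_fraction = 0.25, stem_window = "auto") {
  branch_path <- as_coord_matrix(branch_path)
  main_stem_path <- as_coord_matrix(main_stem_path)
  nb <- nrow(branch_path)
  if (nb < 2) stop("a branch path needs at least 2 nodes")
  base <- branch_path[nb, ]
  if (is.null(base_row)) {
    d2 <- colSums((t(main_stem_path) - base)^2)
    base_row <- which.min(d2)
  }
  # branch direction: walk from the base toward the tip until the secant
  # spans arc_fraction of the branch arc length
  seg <- sqrt(rowSums(diff(branch_path)^2))
  total <- sum(seg)
  arc_from_base <- c(rev(cumsum(rev(seg))), 0) # arc distance of each node from base
  target <- arc_fraction * total
  irow <- max(which(arc_from_base >= target))
  u <- branch_path[irow, ] - base
  # local stem direction, oriented toward the tassel top (decreasing row)
  stem_seg <- sqrt(rowSums(diff(main_stem_path)^2))
  if (identical(stem_window, "auto"))
    stem_window <- 5 * stats::median(stem_seg)
  upward <- rev(cumsum(rev(stem_seg[seq_len(max(base_row - 1, 0))])))
  jrow <- if (base_row == 1) 1
    else {
      cand <- which(upward >= stem_window)
      if (length(cand)) max(cand) else 1
    }
  v <- main_stem_path[jrow, ] - main_stem_path[base_row, ]
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("degenerate branch: zero-length direction vector")
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Tassel convex-hull volume
#'
#' @param full_cloud a [point_cloud()] or coordinate matrix of the whole
#'   tassel.
#' @return hull volume in cm^3; degenerate clouds return 0 with a warning.
#' @export
tassel_volume <- function(full_cloud) {
  v <- convex_hull_volume(full_cloud)
  if (v == 0) warning("degenerate cloud: convex hull volume is 0")
  v
}

#' Tassel dispersion
#'
#' Mean branch insertion angle (in radians) divided by pi/2; 1 means the
#' branches are on average perpendicular to the stem.
#'
#' @param branch_angles branch angles in degrees (at least one).
#' @return dimensionless ratio.
#' @export
tassel_dispersion <- function(branch_angles) {
  if (!length(branch_angles)) stop("need at least one branch angle")
  mean(branch_angles * pi / 180) / (pi / 2)
}

#' Assemble the six-trait record of one tassel
#'
#' Computes branch count, per-branch lengths, insertion angles and
#' curvatures (main stem excluded), convex-hull volume and dispersion.
#' The branch count is the number of non-stem tip instances; in the
#' degenerate single-instance case (the lone path is the stem) the count
#' reports that one cluster and the per-branch lists are empty, with
#' dispersion `NA`.
#'
#' @param full_cloud the tassel [point_cloud()].
#' @param branches a `branch_set` from [extract_branch_paths()].
#' @param instances the `tip_instance_set` the branches were derived from.
#' @param arc_fraction,stem_window see [branch_angle()].
#' @return a `trait_record`: list with `branch_count`, `branch_lengths`,
#'   `branch_angles`, `branch_curvatures`, `tassel_volume`,
#'   `tassel_dispersion` and `branch_instance`.
#' @export
extract_traits <- function(full_cloud, branches, instances,
                           arc_fraction = 0.25, stem_window = "auto") {
  nb <- length(branches$polylines)
  lengths <- numeric(nb)
  angles <- numeric(nb)
  curv <- numeric(nb)
  for (b in seq_len(nb)) {
    poly <- branches$polylines[[b]]
    lengths[b] <- branch_length(poly)
    curv[b] <- branch_curvature(poly)
    angles[b] <- branch_angle(poly, branches$stem_polyline,
                              base_row = branches$stem_base_row[b],
                              arc_fraction = arc_fraction,
                              stem_window = stem_window)
  }
  count <- if (instances$n_instances == 1L) 1L else nb
  structure(list(
    branch_count = as.integer(count),
    branch_lengths = lengths,
    branch_angles = angles,
    branch_curvatures = curv,
    tassel_volume = suppressWarnings(tassel_volume(full_cloud)),
    tassel_dispersion = if (nb > 0) tassel_dispersion(angles) else NA_real_,
    branch_instance = branches$branch_instance
  ), class = "trait_record")
}

#' One-row data frame summary of a trait record
#'
#' @param traits a `trait_record`.
#' @param tassel_id identifier for the row.
#' @return data frame with stable column order: `tassel_id, branch_count,
#'   branch_length_mean, branch_length_sd, branch_angle_mean,
#'   branch_angle_sd, branch_curvature_mean, branch_curvature_sd,
#'   tassel_volume_cm3, tassel_dispersion`.
#' @export
trait_row <- function(traits, tassel_id = NA) {
  msd <- function(x) if (length(x)) c(mean(x), stats::sd(x)) else c(NA_real_, NA_real_)
  l <- msd(traits$branch_lengths)
  a <- msd(traits$branch_angles)
  k <- msd(traits$branch_curvatures)
  data.frame(tassel_id = tassel_id,
             branch_count = traits$branch_count,
             branch_length_mean = l[1], branch_length_sd = l[2],
             branch_angle_mean = a[1], branch_angle_sd = a[2],
             branch_curvature_mean = k[1], branch_curvature_sd = k[2],
             tassel_volume_cm3 = traits$tassel_volume,
             tassel_dispersion = traits$tassel_dispersion)
}
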