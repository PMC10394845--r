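#' Point cloud container
#'
#' The universal currency of the pipeline: an `N x 3` coordinate matrix in
#' centimetres with optional per-point color, normal, class-label and
#' instance-id channels. All stages consume and produce this structure.
#'
#' @param coords numeric matrix with 3 columns (x, y, z in cm).
#' @param colors optional `N x 3` matrix of RGB values in `[0, 1]`.
#' @param normals optional `N x 3` matrix of unit normal vectors.
#' @param labels optional integer vector of per-point class labels
#'   (1 = branch top, 0 = remainder).
#' @param instance optional integer vector of per-point instance ids
#'   (-1 = noise/unassigned).
#'
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(coords, colors = NULL, normals = NULL,
                        labels = NULL, instance = NULL) {
  coords <- as_coord_matrix(coords)
  pc <- structure(
    list(coords = coords, colors = colors, normals = normals,
         labels = labels, instance = instance),
    class = "point_cloud"
  )
  validate_point_cloud(pc)
  pc
}

as_coord_matrix <- function(coords) {
  if (is.data.frame(coords)) coords <- as.matrix(coords)
  if (!is.matrix(coords)) coords <- matrix(coords, ncol = 3)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  coords
}

#' Validate a point cloud's invariants
#'
#' Checks the structural invariants: at least one point, finite coordinates,
#' colors within `[0, 1]`, unit normals (within 1e-6) and channel lengths
#' matching the number of points.
#'
#' @param pc a [point_cloud()].
#' @return `pc`, invisibly; errors on violation.
#' @export
validate_point_cloud <- function(pc) {
  stopifnot(inherits(pc, "point_cloud"))
  n <- nrow(pc$coords)
  if (is.null(n) || n < 1L) stop("point cloud must contain at least one point")
  if (ncol(pc$coords) != 3L) stop("coords must have 3 columns")
  if (!all(is.finite(pc$coords))) stop("coords must be finite")
  if (!is.null(pc$colors)) {
    if (nrow(pc$colors) != n || ncol(pc$colors) != 3L)
      stop("colors must be an N x 3 matrix")
    if (min(pc$colors) < -1e-9 || max(pc$colors) > 1 + 1e-9)
      stop("colors must lie in [0, 1]")
  }
  if (!is.null(pc$normals)) {
    if (nrow(pc$normals) != n || ncol(pc$normals) != 3L)
      stop("normals must be an N x 3 matrix")
    len <- sqrt(rowSums(pc$normals^2))
    if (any(abs(len - 1) > 1e-6))
      stop("normals must have unit length (within 1e-6)")
  }
  for (ch in c("labels", "instance")) {
    v <- pc[[ch]]
    if (!is.null(v) && length(v) != n)
      stop(sprintf("%s length must equal the number of points", ch))
  }
  invisible(pc)
}

#' Number of points in a cloud
#' @param pc a [point_cloud()].
#' @return integer point count.
#' @export
n_points <- function(pc) nrow(pc$coords)

#' Subset a point cloud by index, keeping all channels consistent
#'
#' @param pc a [point_cloud()].
#' @param idx integer (or logical) index vector.
#' @return the subset [point_cloud()].
#' @export
subset_cloud <- function(pc, idx) {
  structure(
    list(coords = pc$coords[idx, , drop = FALSE],
         colors = if (!is.null(pc$colors)) pc$colors[idx, , drop = FALSE],
         normals = if (!is.null(pc$normals)) pc$normals[idx, , drop = FALSE],
         labels = if (!is.null(pc$labels)) pc$labels[idx],
         instance = if (!is.null(pc$instance)) pc$instance[idx]),
    class = "point_cloud"
  )
}

#' @export
print.point_cloud <- function(x, ...) {
  chans <- c(
    if (!is.null(x$colors)) "colors",
    if (!is.null(x$normals)) "normals",
    if (!is.null(x$labels)) "labels",
    if (!is.null(x$instance)) "instance"
  )
  cat(sprintf("<point_cloud> %d points%s\n", nrow(x$coords),
              if (length(chans)) paste0(" + ", paste(chans, collapse = ", "))
              else ""))
  invisible(x)
}
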