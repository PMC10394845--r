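#' Parametric tassel specification
#'
#' The stated world of the generator: a near-vertical main stem (spindle)
#' bearing lateral branches on its upper half, each branch a quadratic
#' Bezier curve with a programmed insertion angle and curvature factor,
#' surfaces emulated by dense arc-uniform sampling with isotropic Gaussian
#' jitter. Ranges are `c(min, max)`; a length-1 value pins the parameter.
#'
#' @param n_branches branch-count range (default 6-16).
#' @param stem_length stem length range in cm (default 25-40).
#' @param branch_length branch length range in cm (default 10-30).
#' @param insertion_angle insertion-angle range in degrees (default 20-60).
#' @param curvature_factor arc/chord ratio range, >= 1 (default 1.0-1.4).
#' @param points_per_cm sampling density along each organ (default 40).
#' @param radial_jitter_sd isotropic jitter SD in cm emulating surface
#'   thickness and reconstruction fuzz (default 0.15; 0 = noiseless).
#' @param tip_label_length length of the labeled distal segment in cm; must
#'   respect the 3-5 cm annotation convention (default 4).
#' @param outlier_fraction fraction of additional far-outlier points placed
#'   uniformly in the 1.5x bounding box (default 0).
#' @param seed integer seed; generation is deterministic per seed.
#' @return a `tassel_spec` list.
#' @export
tassel_spec <- function(n_branches = c(6, 16), stem_length = c(25, 40),
                        branch_length = c(10, 30), insertion_angle = c(20, 60),
                        curvature_factor = c(1.0, 1.4), points_per_cm = 40,
                        radial_jitter_sd = 0.15, tip_label_length = 4,
                        outlier_fraction = 0, seed = 1L) {
  rng <- function(x) if (length(x) == 1) c(x, x) else x
  spec <- list(n_branches = rng(n_branches), stem_length = rng(stem_length),
               branch_length = rng(branch_length),
               insertion_angle = rng(insertion_angle),
               curvature_factor = rng(curvature_factor),
               points_per_cm = points_per_cm,
               radial_jitter_sd = radial_jitter_sd,
               tip_label_length = tip_label_length,
               outlier_fraction = outlier_fraction, seed = as.integer(seed))
  for (f in c("n_branches", "stem_length", "branch_length", "insertion_angle",
              "curvature_factor"))
    if (spec[[f]][1] > spec[[f]][2]) stop(f, " range must be ordered")
  if (spec$curvature_factor[1] < 1) stop("curvature_factor must be >= 1")
  if (points_per_cm <= 0) stop("points_per_cm must be positive")
  if (radial_jitter_sd < 0) stop("radial_jitter_sd must be >= 0")
  if (tip_label_length < 3 || tip_label_length > 5)
    stop("tip_label_length must respect the 3-5 cm annotation convention")
  if (outlier_fraction < 0 || outlier_fraction > 1)
    stop("outlier_fraction must lie in [0, 1]")
  structure(spec, class = "tassel_spec")
}

# quadratic Bezier evaluated at parameter values t (vector)
bezier_eval <- function(P0, P1, P2, t) {
  outer((1 - t)^2, P0) + outer(2 * t * (1 - t), P1) + outer(t^2, P2)
}

# fine cumulative arc length over a uniform t grid
bezier_arc_table <- function(P0, P1, P2, n_grid = 2000L) {
  t <- seq(0, 1, length.out = n_grid + 1L)
  pts <- bezier_eval(P0, P1, P2, t)
  seg <- sqrt(rowSums(diff(pts)^2))
  list(t = t, cum = c(0, cumsum(seg)), pts = pts)
}

# arc/chord ratio of the canonical 2-D shape: P0 = origin, tangent +x,
# control point at mu along the tangent, chord of length 1 rotated gamma
# below the tangent
shape_ratio <- function(gamma, mu = 0.9) {
  P2 <- c(cos(gamma), -sin(gamma))
  P1 <- c(mu, 0)
  tab <- bezier_arc_table(c(0, 0), P1, P2, 800L)
  max(tab$cum) / 1
}

# solve the droop angle gamma realizing a target arc/chord ratio
solve_gamma <- function(curvature, mu = 0.9) {
  if (curvature <= 1 + 1e-9) return(0)
  hi <- 2.4 # ~137 deg; shape_ratio(hi) > 1.6 at mu = 0.9
  if (shape_ratio(hi, mu) < curvature)
    stop("curvature_factor out of the generator's reachable range")
  stats::uniroot(function(g) shape_ratio(g, mu) - curvature,
                 c(1e-8, hi), tol = 1e-10)$root
}

#' Generate one synthetic tassel with ground truth
#'
#' The main stem is a near-vertical polyline with mild sinusoidal wander;
#' branches attach at sorted random heights on the upper stem half with
#' golden-angle azimuths, each a quadratic Bezier whose control point lies
#' along the drawn insertion-angle direction (so the base tangent realizes
#' the angle exactly) and whose droop realizes the drawn curvature factor,
#' concentrating bending distally as real tassel branches do. Points are
#' sampled uniformly by arc length with isotropic Gaussian jitter; the
#' distal `tip_label_length` of every branch and of the spindle is
#' tip-labeled (the spindle top is morphologically a branch top). Colors
#' fall in a green-yellow HSV band that passes the default foreground mask;
#' optional outliers are uniform in the 1.5x bounding box with a red hue
#' that does not.
#'
#' @param spec a [tassel_spec()].
#' @return list with `cloud` (a labeled, colored [point_cloud()]) and
#'   `truth` (per-branch table with analytic length/angle/curvature,
#'   per-point `branch_id` (-2 = stem, -1 = outlier) and `tip` flag, and the
#'   implied `traits` record).
#' @export
generate_tassel <- function(spec = tassel_spec()) {
  withr_seed(spec$seed, {
    B <- if (spec$n_branches[1] == spec$n_branches[2]) spec$n_branches[1]
      else sample(spec$n_branches[1]:spec$n_branches[2], 1)
    if (B > 24)
      stop("infeasible geometry: azimuths overlap; lower n_branches (<= 24)")
    s <- stats::runif(1, spec$stem_length[1], spec$stem_length[2])

    # stem centerline: unit-speed-in-z with sinusoidal lateral wander
    amp <- stats::runif(2, 0.05, 0.25)
    phase <- stats::runif(2, 0, 2 * pi)
    stem_xy <- function(z)
      cbind(amp[1] * sin(2 * pi * z / s + phase[1]),
            amp[2] * sin(2 * pi * z / s + phase[2]))
    stem_tangent <- function(z) {
      d <- cbind(amp[1] * (2 * pi / s) * cos(2 * pi * z / s + phase[1]),
                 amp[2] * (2 * pi / s) * cos(2 * pi * z / s + phase[2]), 1)
      d / sqrt(rowSums(d^2))
    }
    stem_point <- function(z) cbind(stem_xy(z), z)

    attach_z <- sort(stats::runif(B, 0.5 * s, 0.85 * s))
    azim <- (seq_len(B) - 1) * 137.508 * pi / 180 +
      stats::runif(B, -15, 15) * pi / 180
    theta <- stats::runif(B, spec$insertion_angle[1], spec$insertion_angle[2])
    Ls <- stats::runif(B, spec$branch_length[1], spec$branch_length[2])
    curv <- stats::runif(B, spec$curvature_factor[1], spec$curvature_factor[2])

    coords <- list()
    branch_id <- list()
    tip <- list()
    per_branch <- data.frame()

    # stem samples (id -2), spindle top tip-labeled; stratified-uniform arc
    # positions emulate dense non-uniform surface sampling (and keep FPS
    # well-conditioned: perfectly regular spacing makes maximin selection
    # degenerate)
    n_stem <- max(2L, round(s * spec$points_per_cm))
    z <- (seq_len(n_stem) - stats::runif(n_stem)) / n_stem * s
    coords[[1]] <- stem_point(z)
    branch_id[[1]] <- rep(-2L, n_stem)
    tip[[1]] <- as.integer(s - z <= spec$tip_label_length)

    mu <- 0.9 # shape constant: control point far along the tangent
    for (i in seq_len(B)) {
      P0 <- as.numeric(stem_point(attach_z[i]))
      that <- as.numeric(stem_tangent(attach_z[i]))
      h0 <- c(cos(azim[i]), sin(azim[i]), 0)
      h <- h0 - sum(h0 * that) * that
      h <- h / sqrt(sum(h^2))
      th <- theta[i] * pi / 180
      d <- cos(th) * that + sin(th) * h
      gamma <- solve_gamma(curv[i], mu)
      e <- cos(th + gamma) * that + sin(th + gamma) * h
      X <- Ls[i] / max(shape_ratio(gamma, mu), 1) # chord so that arc = L
      P1 <- P0 + mu * X * d
      P2 <- P0 + X * e
      tab <- bezier_arc_table(P0, P1, P2)
      arc <- max(tab$cum)
      n_b <- max(2L, round(arc * spec$points_per_cm))
      a_pos <- (seq_len(n_b) - stats::runif(n_b)) / n_b * arc
      t_pos <- stats::approx(tab$cum, tab$t, xout = a_pos)$y
      coords[[i + 1L]] <- bezier_eval(P0, P1, P2, t_pos)
      branch_id[[i + 1L]] <- rep(i - 1L, n_b)
      tip[[i + 1L]] <- as.integer(arc - a_pos <= spec$tip_label_length)
      chord <- sqrt(sum((P2 - P0)^2))
      per_branch <- rbind(per_branch, data.frame(
        branch = i - 1L, length = arc, angle = theta[i],
        curvature = arc / chord, attach_height = attach_z[i],
        azimuth = azim[i] * 180 / pi))
    }

    coords <- do.call(rbind, coords)
    branch_id <- unlist(branch_id)
    tip <- unlist(tip)
    n_clean <- nrow(coords)
    if (spec$radial_jitter_sd > 0)
      coords <- coords + matrix(stats::rnorm(3 * n_clean,
                                             sd = spec$radial_jitter_sd),
                                n_clean, 3)

    # colors: green-yellow band passing the default HSV mask
    cols <- t(grDevices::col2rgb(grDevices::hsv(
      stats::runif(n_clean, 60, 120) / 360,
      stats::runif(n_clean, 0.4, 0.95),
      stats::runif(n_clean, 0.5, 1)))) / 255

    n_out <- round(spec$outlier_fraction * n_clean)
    if (n_out > 0) {
      lo <- apply(coords, 2, min)
      hi <- apply(coords, 2, max)
      mid <- (lo + hi) / 2
      half <- pmax((hi - lo) / 2 * 1.5, 1)
      out_pts <- sapply(1:3, function(j)
        stats::runif(n_out, mid[j] - half[j], mid[j] + half[j]))
      if (n_out == 1) out_pts <- matrix(out_pts, 1, 3)
      out_cols <- t(grDevices::col2rgb(grDevices::hsv(
        stats::runif(n_out, 0, 20) / 360,
        stats::runif(n_out, 0.5, 1),
        stats::runif(n_out, 0.3, 1)))) / 255
      coords <- rbind(coords, out_pts)
      cols <- rbind(cols, out_cols)
      branch_id <- c(branch_id, rep(-1L, n_out))
      tip <- c(tip, rep(0L, n_out))
    }

    cloud <- point_cloud(coords, colors = cols, labels = tip,
                         instance = branch_id)
    clean <- seq_len(n_clean)
    angles <- per_branch$angle
    truth <- list(
      per_branch = per_branch,
      per_point = data.frame(branch_id = branch_id, tip = tip),
      stem_length = s,
      n_outliers = n_out,
      traits = list(
        branch_count = B,
        branch_lengths = per_branch$length,
        branch_angles = angles,
        branch_curvatures = per_branch$curvature,
        tassel_volume = convex_hull_volume(coords[clean, , drop = FALSE]),
        tassel_dispersion = if (B > 0) tassel_dispersion(angles) else NA_real_
      )
    )
    list(cloud = cloud, truth = truth)
  })
}

#' Generate a directory of labeled tassels with a ground-truth manifest
#'
#' Writes `tassel_<i>.ply` (labels = tip flags, instance = true branch ids)
#' plus `manifest.csv` (one [trait_row()] per tassel with the generator's
#' analytic values) and `branches.csv` (long format, one row per branch).
#' Per-tassel seeds derive deterministically from `seed`.
#'
#' @param n_tassels number of tassels.
#' @param spec a [tassel_spec()] serving as the range template.
#' @param dir output directory (created if missing).
#' @param seed master seed.
#' @return the manifest data frame, invisibly.
#' @export
generate_dataset <- function(n_tassels, spec = tassel_spec(), dir, seed = 1L) {
  if (n_tassels < 1) stop("n_tassels must be >= 1")
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create directory: ", dir)
  manifest <- data.frame()
  branches <- data.frame()
  for (i in seq_len(n_tassels)) {
    sp <- spec
    sp$seed <- as.integer(seed + 101L * i)
    gt <- generate_tassel(sp)
    f <- file.path(dir, sprintf("tassel_%03d.ply", i))
    write_point_cloud(gt$cloud, f, format = "ply")
    tr <- structure(c(gt$truth$traits, list(branch_instance = integer(0))),
                    class = "trait_record")
    row <- trait_row(tr, tassel_id = sprintf("tassel_%03d", i))
    row$file <- basename(f)
    row$seed <- sp$seed
    manifest <- rbind(manifest, row)
    pb <- gt$truth$per_branch
    pb$tassel_id <- sprintf("tassel_%03d", i)
    branches <- rbind(branches, pb)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(branches, file.path(dir, "branches.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Resampling augmentation
#'
#' The dataset-enhancement mechanism: `n_copies` independent seeded random
#' subsamples of size `target_n`, labels and channels carried along. Copy
#' `i` uses `seed + i`.
#'
#' @param cloud a labeled [point_cloud()].
#' @param target_n points per copy (`<= N`).
#' @param n_copies number of copies.
#' @param seed base seed.
#' @return list of `n_copies` [point_cloud()]s.
#' @export
resample_augment <- function(cloud, target_n, n_copies = 1L, seed = 1L) {
  if (target_n > n_points(cloud)) stop("target_n must be <= N")
  lapply(seq_len(n_copies), function(i)
    random_downsample(cloud, target_n, seed = seed + i))
}
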