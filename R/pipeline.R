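#' Pipeline configuration
#'
#' Nested defaults for every stage. Where the method prescribes a value the
#' default equals it: outlier filter n = 20, alpha = 0.5; clustering
#' minPts = 5 with the adaptive radius eps = 3 x mean nearest-neighbor
#' distance; working resolution 4000 points; batch 24 / lr 0.001 halved
#' every 20 epochs on the training side.
#'
#' @param ... named overrides; nested lists are merged field-by-field (e.g.
#'   `preprocess = list(fps_n = 2000)`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    verbose = FALSE,
    preprocess = list(
      hsv = TRUE, hsv_range = hsv_range(),
      sor = TRUE, sor_neighbors = 20L, sor_alpha = 0.5,
      random_n = 100000L, fps_n = 4000L, normals_k = 16L
    ),
    cluster = list(eps = "auto", min_pts = 5L, min_cluster_size = 10L),
    skeleton = list(nodes = 2048L, radius = "auto", radius_growth = 1.5,
                    stem_rule = "straightest", turn_window = 2,
                    turn_threshold = 15),
    traits = list(arc_fraction = 0.25, stem_window = "auto")
  )
  cfg <- merge_config(cfg, list(...))
  structure(cfg, class = "pipeline_config")
}

merge_config <- function(base, upd) {
  for (nm in names(upd)) {
    if (is.list(upd[[nm]]) && is.list(base[[nm]]) &&
        !inherits(upd[[nm]], c("hsv_range")))
      base[[nm]] <- merge_config(base[[nm]], upd[[nm]])
    else base[[nm]] <- upd[[nm]]
  }
  base
}

#' Read a pipeline configuration from JSON
#'
#' The file mirrors [pipeline_config()] field-for-field; absent fields keep
#' their defaults.
#'
#' @param path JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  upd <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, upd)
}

log_msg <- function(cfg, ...) {
  if (isTRUE(cfg$verbose)) message(sprintf(...))
}

#' Run the full pipeline on one tassel or a directory
#'
#' Executes preprocessing (HSV foreground mask, statistical outlier
#' removal, random + farthest-point downsampling), tip labeling (a trained
#' network checkpoint, an in-memory model, or `"ground-truth-tips"` which
#' passes through the labels already on the cloud), density clustering of
#' the tips, skeleton extraction, branch fusion and trait computation.
#'
#' @param input a [point_cloud()], a PLY/xyz file path, or a directory of
#'   PLY files.
#' @param config a [pipeline_config()].
#' @param checkpoint `"ground-truth-tips"`, a `tipnet_model`, or the path of
#'   a [save_tipnet()] checkpoint.
#' @param output_dir optional directory for stage artifacts (labeled and
#'   segmented PLYs, skeleton JSON, traits CSV).
#' @param keep_going with a directory input, continue past per-tassel
#'   failures (failed tassels are reported and skipped).
#' @return for a single tassel, a list with the working cloud, instances,
#'   tree, branches, per-point membership and `traits`; for a directory, a
#'   list with per-tassel `results` and the combined `traits_table`.
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         checkpoint = "ground-truth-tips",
                         output_dir = NULL, keep_going = FALSE) {
  if (is.character(input) && length(input) == 1 && dir.exists(input)) {
    files <- sort(list.files(input, pattern = "\\.ply$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stop("no PLY files in ", input)
    results <- list()
    rows <- data.frame()
    for (f in files) {
      id <- sub("\\.ply$", "", basename(f), ignore.case = TRUE)
      res <- tryCatch(
        run_pipeline(f, config, checkpoint, output_dir = output_dir),
        error = function(e) {
          msg <- sprintf("tassel %s failed: %s", id, conditionMessage(e))
          if (!keep_going) stop(msg, call. = FALSE)
          warning(msg, call. = FALSE)
          NULL
        })
      if (is.null(res)) next
      results[[id]] <- res
      rows <- rbind(rows, trait_row(res$traits, tassel_id = id))
    }
    if (!is.null(output_dir))
      utils::write.csv(rows, file.path(output_dir, "traits.csv"),
                       row.names = FALSE)
    return(list(results = results, traits_table = rows))
  }

  tassel_id <- "tassel"
  if (is.character(input)) {
    tassel_id <- sub("\\.(ply|xyz|txt)$", "", basename(input), ignore.case = TRUE)
    input <- read_point_cloud(input)
  }
  cloud <- input
  validate_point_cloud(cloud)
  pp <- config$preprocess
  t0 <- proc.time()[3]

  if (isTRUE(pp$hsv) && !is.null(cloud$colors)) {
    mask <- hsv_foreground_mask(cloud, pp$hsv_range)
    if (!any(mask)) stop("stage preprocess [", tassel_id,
                         "]: HSV mask removed every point")
    cloud <- subset_cloud(cloud, mask)
    log_msg(config, "hsv mask kept %d points", n_points(cloud))
  }
  if (isTRUE(pp$sor) && n_points(cloud) > pp$sor_neighbors) {
    flt <- statistical_outlier_filter(
      cloud, outlier_filter_params(pp$sor_neighbors, pp$sor_alpha))
    cloud <- flt$kept
    log_msg(config, "outlier filter removed %d points", length(flt$removed))
  }
  if (n_points(cloud) > pp$random_n)
    cloud <- random_downsample(cloud, pp$random_n, seed = config$seed)
  if (n_points(cloud) > pp$fps_n)
    cloud <- subset_cloud(cloud, sort(farthest_point_sample(cloud, pp$fps_n)))
  log_msg(config, "working resolution: %d points", n_points(cloud))

  if (identical(checkpoint, "ground-truth-tips")) {
    if (is.null(cloud$labels))
      stop("stage segment [", tassel_id,
           "]: ground-truth-tips mode needs a labels channel")
  } else {
    model <- if (inherits(checkpoint, "tipnet_model")) checkpoint
      else load_tipnet(checkpoint)
    cloud <- predict_tips(model, cloud)
  }

  tip_idx <- which(cloud$labels == 1L)
  if (!length(tip_idx))
    stop("stage cluster [", tassel_id, "]: no tip points")
  tips <- subset_cloud(cloud, tip_idx)
  instances <- density_cluster(
    tips, cluster_params(config$cluster$eps, config$cluster$min_pts,
                         config$cluster$min_cluster_size))
  if (instances$n_instances < 1)
    stop("stage cluster [", tassel_id, "]: no instance survived")
  log_msg(config, "clustering: %d instances", instances$n_instances)

  # remainder = non-tip points plus tip points rejected as noise
  rem_idx <- c(which(cloud$labels != 1L), tip_idx[instances$instance_ids == -1L])
  rem_idx <- sort(rem_idx)
  remainder <- subset_cloud(cloud, rem_idx)
  node_idx <- if (n_points(remainder) > config$skeleton$nodes)
    sort(farthest_point_sample(remainder, config$skeleton$nodes))
    else seq_len(n_points(remainder))
  nodes <- subset_cloud(remainder, node_idx)

  growth <- initial_growth_points(nodes, instances)
  root <- select_root(nodes, growth)
  tree <- build_spanning_tree(nodes, root, radius = config$skeleton$radius,
                              radius_growth = config$skeleton$radius_growth)
  branches <- extract_branch_paths(
    tree, growth, instances,
    stem_rule = config$skeleton$stem_rule,
    turn_window = config$skeleton$turn_window,
    turn_threshold = config$skeleton$turn_threshold)
  membership <- assign_points_to_branches(cloud, branches)
  traits <- extract_traits(cloud, branches, instances,
                           arc_fraction = config$traits$arc_fraction,
                           stem_window = config$traits$stem_window)
  log_msg(config, "pipeline done in %.2f s: %d branches",
          proc.time()[3] - t0, length(branches$polylines))

  res <- list(cloud = cloud, tip_idx = tip_idx, instances = instances,
              nodes = nodes, tree = tree, branches = branches,
              membership = membership, traits = traits)
  if (!is.null(output_dir)) write_stage_artifacts(res, tassel_id, output_dir)
  res
}

write_stage_artifacts <- function(res, tassel_id, output_dir) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  seg <- res$cloud
  inst_full <- rep(-1L, n_points(seg))
  inst_full[res$tip_idx] <- res$instances$instance_ids
  seg$instance <- inst_full
  write_point_cloud(seg, file.path(output_dir,
                                   paste0(tassel_id, "_segmented.ply")))
  fused <- res$cloud
  fused$instance <- as.integer(res$membership)
  write_point_cloud(fused, file.path(output_dir,
                                     paste0(tassel_id, "_branches.ply")))
  skel <- list(
    nodes = unname(apply(res$tree$node_coords, 1, function(r) as.list(r))),
    parent = res$tree$parent,
    root = res$tree$root,
    main_stem = res$branches$main_stem,
    paths = res$branches$paths
  )
  jsonlite::write_json(skel, file.path(output_dir,
                                       paste0(tassel_id, "_skeleton.json")),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(trait_row(res$traits, tassel_id),
                   file.path(output_dir, paste0(tassel_id, "_traits.csv")),
                   row.names = FALSE)
  invisible(output_dir)
}
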