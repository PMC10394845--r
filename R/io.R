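#' Read a point cloud from disk
#'
#' Supports PLY (ASCII and binary little-endian) and whitespace-delimited
#' text. The PLY dialect uses vertex properties
#' `x y z [red green blue] [nx ny nz] [label] [instance]`; colors are stored
#' as uchar 0-255 and converted to `[0, 1]` on read. Text rows are
#' `x y z [r g b] [label]` with colors already in `[0, 1]`.
#'
#' @param path file path.
#' @param format `"ply"` or `"xyz-text"`; default guesses from the extension.
#' @return a [point_cloud()]; channels are populated iff present in the file.
#' @export
read_point_cloud <- function(path, format = c("auto", "ply", "xyz-text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz-text"
  }
  if (file.size(path) == 0) stop("empty file: ", path)
  if (format == "ply") read_ply(path) else read_xyz_text(path)
}

#' Write a point cloud to disk
#'
#' The file is re-readable by [read_point_cloud()] with equal content (exact
#' for labels/instances, to float precision for coordinates; PLY colors are
#' quantized to uchar 0-255 per the package's PLY dialect).
#'
#' @param cloud a [point_cloud()].
#' @param path output file path.
#' @param format `"ply"` or `"xyz-text"`; default guesses from the extension.
#' @param binary for PLY, write `binary_little_endian` instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = c("auto", "ply", "xyz-text"),
                              binary = FALSE) {
  format <- match.arg(format)
  validate_point_cloud(cloud)
  if (format == "auto") {
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz-text"
  }
  if (format == "ply") write_ply(cloud, path, binary = binary)
  else write_xyz_text(cloud, path)
  invisible(path)
}

# --- PLY -------------------------------------------------------------------

ply_type_info <- function(type) {
  switch(type,
    char = , int8 = list(what = "integer", size = 1L, signed = TRUE),
    uchar = , uint8 = list(what = "integer", size = 1L, signed = FALSE),
    short = , int16 = list(what = "integer", size = 2L, signed = TRUE),
    ushort = , uint16 = list(what = "integer", size = 2L, signed = FALSE),
    int = , int32 = list(what = "integer", size = 4L, signed = TRUE),
    uint = , uint32 = list(what = "integer", size = 4L, signed = FALSE),
    float = , float32 = list(what = "double", size = 4L, signed = TRUE),
    double = , float64 = list(what = "double", size = 8L, signed = TRUE),
    stop("unsupported PLY property type: ", type)
  )
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0) stop("PLY parse error: end of file inside header")
    header <- c(header, line)
    if (identical(trimws(line), "end_header")) break
    if (length(header) > 1000) stop("PLY parse error: header too long")
  }
  if (trimws(header[1]) != "ply")
    stop("PLY parse error at line 1: missing 'ply' magic")
  fmt_line <- grep("^format ", trimws(header), value = TRUE)
  if (length(fmt_line) != 1)
    stop("PLY parse error: missing/duplicate format line")
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)

  elements <- list()
  cur <- NULL
  for (i in seq_along(header)) {
    toks <- strsplit(trimws(header[i]), "\\s+")[[1]]
    if (!length(toks)) next
    if (toks[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = toks[2], count = as.integer(toks[3]), props = list())
    } else if (toks[1] == "property") {
      if (is.null(cur))
        stop(sprintf("PLY parse error at line %d: property outside element", i))
      if (toks[2] == "list")
        stop(sprintf("PLY parse error at line %d: list properties unsupported", i))
      cur$props[[length(cur$props) + 1L]] <-
        list(type = toks[2], name = toks[length(toks)])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex)) stop("PLY parse error: no vertex element")

  values <- list()
  if (fmt == "ascii") {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    row <- 0L
    for (el in elements) {
      if (el$count == 0) next
      if (row + el$count > length(txt))
        stop("PLY parse error: fewer data rows than declared")
      block <- txt[(row + 1L):(row + el$count)]
      row <- row + el$count
      if (el$name != "vertex") next
      nprop <- length(el$props)
      mat <- matrix(NA_real_, el$count, nprop)
      for (r in seq_len(el$count)) {
        toks <- strsplit(trimws(block[r]), "\\s+")[[1]]
        if (length(toks) != nprop)
          stop(sprintf("PLY parse error at data row %d: expected %d values, got %d",
                       r, nprop, length(toks)))
        v <- suppressWarnings(as.numeric(toks))
        if (anyNA(v))
          stop(sprintf("PLY parse error at data row %d: non-numeric value", r))
        mat[r, ] <- v
      }
      for (j in seq_len(nprop)) values[[el$props[[j]]$name]] <-
          list(v = mat[, j], type = el$props[[j]]$type)
    }
  } else {
    for (el in elements) {
      infos <- lapply(el$props, function(p) ply_type_info(p$type))
      rec <- sum(vapply(infos, function(x) x$size, 1L))
      raw <- readBin(con, "raw", n = rec * el$count)
      if (length(raw) < rec * el$count)
        stop("PLY parse error: truncated binary data for element ", el$name)
      if (el$name != "vertex") next
      rawm <- matrix(raw, nrow = rec)
      off <- 0L
      for (j in seq_along(el$props)) {
        info <- infos[[j]]
        bytes <- as.raw(rawm[(off + 1L):(off + info$size), , drop = FALSE])
        v <- readBin(bytes, what = info$what, n = el$count, size = info$size,
                     signed = if (info$size < 4) info$signed else TRUE,
                     endian = "little")
        values[[el$props[[j]]$name]] <- list(v = as.numeric(v),
                                             type = el$props[[j]]$type)
        off <- off + info$size
      }
    }
  }

  for (ax in c("x", "y", "z"))
    if (is.null(values[[ax]])) stop("PLY parse error: missing vertex property ", ax)
  coords <- cbind(values$x$v, values$y$v, values$z$v)
  colors <- NULL
  if (!is.null(values$red) && !is.null(values$green) && !is.null(values$blue)) {
    colors <- cbind(values$red$v, values$green$v, values$blue$v)
    if (ply_type_info(values$red$type)$size == 1L) colors <- colors / 255
  }
  normals <- NULL
  if (!is.null(values$nx) && !is.null(values$ny) && !is.null(values$nz))
    normals <- cbind(values$nx$v, values$ny$v, values$nz$v)
  labels <- if (!is.null(values$label)) as.integer(values$label$v)
  instance <- if (!is.null(values$instance)) as.integer(values$instance$v)
  point_cloud(coords, colors = colors, normals = normals,
              labels = labels, instance = instance)
}

write_ply <- function(cloud, path, binary = FALSE) {
  n <- n_points(cloud)
  props <- c("property double x", "property double y", "property double z")
  if (!is.null(cloud$colors))
    props <- c(props, "property uchar red", "property uchar green",
               "property uchar blue")
  if (!is.null(cloud$normals))
    props <- c(props, "property double nx", "property double ny",
               "property double nz")
  if (!is.null(cloud$labels)) props <- c(props, "property int label")
  if (!is.null(cloud$instance)) props <- c(props, "property int instance")
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    "comment written by tasselseg",
    sprintf("element vertex %d", n),
    props,
    "end_header"
  )
  col255 <- if (!is.null(cloud$colors))
    matrix(as.integer(round(cloud$colors * 255)), ncol = 3)

  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (binary) {
    # build each property as a (bytes x n) raw matrix and interleave by row-bind
    as_raw_mat <- function(v, what, size) {
      r <- writeBin(v, raw(), size = size, endian = "little")
      matrix(r, nrow = size)
    }
    blocks <- list(as_raw_mat(as.numeric(cloud$coords[, 1]), "double", 8),
                   as_raw_mat(as.numeric(cloud$coords[, 2]), "double", 8),
                   as_raw_mat(as.numeric(cloud$coords[, 3]), "double", 8))
    if (!is.null(cloud$colors))
      blocks <- c(blocks, lapply(1:3, function(j)
        matrix(as.raw(col255[, j]), nrow = 1)))
    if (!is.null(cloud$normals))
      blocks <- c(blocks, lapply(1:3, function(j)
        as_raw_mat(as.numeric(cloud$normals[, j]), "double", 8)))
    if (!is.null(cloud$labels))
      blocks <- c(blocks, list(as_raw_mat(as.integer(cloud$labels), "integer", 4)))
    if (!is.null(cloud$instance))
      blocks <- c(blocks, list(as_raw_mat(as.integer(cloud$instance), "integer", 4)))
    writeBin(as.raw(do.call(rbind, blocks)), con)
  } else {
    cols <- list(format(cloud$coords[, 1], digits = 17, trim = TRUE, scientific = FALSE),
                 format(cloud$coords[, 2], digits = 17, trim = TRUE, scientific = FALSE),
                 format(cloud$coords[, 3], digits = 17, trim = TRUE, scientific = FALSE))
    if (!is.null(cloud$colors))
      cols <- c(cols, list(col255[, 1], col255[, 2], col255[, 3]))
    if (!is.null(cloud$normals))
      cols <- c(cols, lapply(1:3, function(j)
        format(cloud$normals[, j], digits = 17, trim = TRUE, scientific = FALSE)))
    if (!is.null(cloud$labels)) cols <- c(cols, list(as.integer(cloud$labels)))
    if (!is.null(cloud$instance)) cols <- c(cols, list(as.integer(cloud$instance)))
    writeLines(do.call(paste, cols), con, sep = "\n")
  }
  invisible(path)
}

# --- xyz text --------------------------------------------------------------

read_xyz_text <- function(path) {
  df <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "numeric"),
    error = function(e) stop("text parse error in ", path, ": ",
                             conditionMessage(e))
  )
  nc <- ncol(df)
  coords <- unname(as.matrix(df[, 1:3]))
  colors <- NULL
  labels <- NULL
  if (nc == 4) {
    labels <- as.integer(df[[4]])
  } else if (nc == 6) {
    colors <- unname(as.matrix(df[, 4:6]))
  } else if (nc == 7) {
    colors <- unname(as.matrix(df[, 4:6]))
    labels <- as.integer(df[[7]])
  } else if (nc != 3) {
    stop("text parse error: expected 3, 4, 6 or 7 columns, got ", nc)
  }
  point_cloud(coords, colors = colors, labels = labels)
}

write_xyz_text <- function(cloud, path) {
  cols <- list(cloud$coords[, 1], cloud$coords[, 2], cloud$coords[, 3])
  if (!is.null(cloud$colors))
    cols <- c(cols, list(cloud$colors[, 1], cloud$colors[, 2], cloud$colors[, 3]))
  if (!is.null(cloud$labels)) cols <- c(cols, list(as.integer(cloud$labels)))
  num <- lapply(cols, function(v)
    if (is.integer(v)) as.character(v)
    else format(v, digits = 17, trim = TRUE, scientific = FALSE))
  writeLines(do.call(paste, num), path)
  invisible(path)
}
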