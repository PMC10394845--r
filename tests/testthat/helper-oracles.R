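# Brute-force oracles, independent of the package's implementations: plain R,
# exhaustive neighbor scans, no shared code paths with src/kernels.cpp.

dist_matrix <- function(coords) as.matrix(stats::dist(coords))

# statistical outlier filter: per-point mean distance to the n nearest
# neighbors, removal iff above global mean + alpha * sd of those means
oracle_sor_removed <- function(coords, n_neighbors, alpha) {
  d <- dist_matrix(coords)
  mu <- vapply(seq_len(nrow(coords)), function(i) {
    di <- sort(d[i, -i])[seq_len(n_neighbors)]
    mean(di)
  }, numeric(1))
  which(mu > mean(mu) + alpha * stats::sd(mu))
}

# greedy maximin selection, exhaustive candidate scan, lowest-index ties
oracle_fps <- function(coords, target_n, start = 1L) {
  n <- nrow(coords)
  d <- dist_matrix(coords)
  sel <- integer(target_n)
  sel[1] <- start
  mind <- d[, start]
  mind[start] <- -Inf
  for (s in seq_len(target_n - 1L) + 1L) {
    best <- which.max(mind) # which.max takes the first (lowest index) max
    sel[s] <- best
    mind <- pmin(mind, d[, best])
    mind[best] <- -Inf
  }
  sel
}

oracle_mean_nn <- function(coords) {
  d <- dist_matrix(coords)
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

# DBSCAN with the pinned border rule: ascending-index seeds, FIFO expansion,
# neighbor lists ascending; then min-size rejection and renumbering by
# descending size (first-seen breaks ties)
oracle_dbscan <- function(coords, eps, min_pts, min_cluster_size = 1L) {
  n <- nrow(coords)
  d <- dist_matrix(coords)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, 1L) >= min_pts
  ids <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || ids[i] != -1L) next
    ids[i] <- cl
    queue <- i
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      for (v in nb[[u]]) {
        if (ids[v] == -1L) {
          ids[v] <- cl
          if (core[v]) queue <- c(queue, v)
        }
      }
    }
    cl <- cl + 1L
  }
  if (cl > 0L) {
    sizes <- tabulate(ids + 1L, nbins = cl)
    keep <- which(sizes >= min_cluster_size)
    ord <- keep[order(-sizes[keep], keep)]
    remap <- rep(-1L, cl)
    remap[ord] <- seq_along(ord) - 1L
    pos <- ids >= 0L
    ids[pos] <- remap[ids[pos] + 1L]
  }
  ids
}

oracle_confusion <- function(pred, truth, cl) {
  c(tp = sum(pred == cl & truth == cl), fp = sum(pred == cl & truth != cl),
    fn = sum(pred != cl & truth == cl), tn = sum(pred != cl & truth != cl))
}

# O(M^2) Dijkstra on the per-node radius graph (edge iff d <= max(r_i, r_j))
oracle_dijkstra <- function(coords, root, radius) {
  n <- nrow(coords)
  if (length(radius) == 1) radius <- rep(radius, n)
  d <- dist_matrix(coords)
  adj <- d <= outer(radius, radius, pmax)
  dist <- rep(Inf, n)
  dist[root] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    nbs <- which(adj[u, ] & !done)
    relax <- dist[u] + d[u, nbs]
    upd <- relax < dist[nbs]
    dist[nbs[upd]] <- relax[upd]
  }
  dist
}

# --- independent hull volume (pure R beneath-beyond) + Monte-Carlo ----------

# face list of the convex hull: rows (a, b, c) with outward unit normal and
# offset; written independently of the C++ kernel
oracle_hull_faces <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 4)
  ctr <- colMeans(pts)
  ord <- order(-rowSums(sweep(pts, 2, ctr)^2))
  # initial tetrahedron from 4 affinely independent points
  i0 <- ord[1]
  i1 <- which.max(colSums((t(pts) - pts[i0, ])^2))
  v1 <- pts[i1, ] - pts[i0, ]
  a2 <- apply(pts, 1, function(p) {
    cr <- c(v1[2] * (p[3] - pts[i0, 3]) - v1[3] * (p[2] - pts[i0, 2]),
            v1[3] * (p[1] - pts[i0, 1]) - v1[1] * (p[3] - pts[i0, 3]),
            v1[1] * (p[2] - pts[i0, 2]) - v1[2] * (p[1] - pts[i0, 1]))
    sum(cr^2)
  })
  i2 <- which.max(a2)
  nrm <- c(v1[2] * (pts[i2, 3] - pts[i0, 3]) - v1[3] * (pts[i2, 2] - pts[i0, 2]),
           v1[3] * (pts[i2, 1] - pts[i0, 1]) - v1[1] * (pts[i2, 3] - pts[i0, 3]),
           v1[1] * (pts[i2, 2] - pts[i0, 2]) - v1[2] * (pts[i2, 1] - pts[i0, 1]))
  h <- abs(as.numeric(sweep(pts, 2, pts[i0, ]) %*% nrm))
  i3 <- which.max(h)
  if (h[i3] <= 1e-12) stop("degenerate point set in oracle hull")
  O <- colMeans(pts[c(i0, i1, i2, i3), ])
  scale <- max(apply(pts, 2, max) - apply(pts, 2, min))

  face <- function(a, b, c) {
    nn <- c((pts[b, 2] - pts[a, 2]) * (pts[c, 3] - pts[a, 3]) -
              (pts[b, 3] - pts[a, 3]) * (pts[c, 2] - pts[a, 2]),
            (pts[b, 3] - pts[a, 3]) * (pts[c, 1] - pts[a, 1]) -
              (pts[b, 1] - pts[a, 1]) * (pts[c, 3] - pts[a, 3]),
            (pts[b, 1] - pts[a, 1]) * (pts[c, 2] - pts[a, 2]) -
              (pts[b, 2] - pts[a, 2]) * (pts[c, 1] - pts[a, 1]))
    nn <- nn / sqrt(sum(nn^2))
    off <- sum(nn * pts[a, ])
    if (sum(nn * O) > off) {
      tmp <- b; b <- c; c <- tmp
      nn <- -nn; off <- -off
    }
    list(v = c(a, b, c), n = nn, off = off)
  }
  faces <- list(face(i0, i1, i2), face(i0, i1, i3), face(i0, i2, i3),
                face(i1, i2, i3))
  eps <- 1e-9 * scale
  for (i in setdiff(ord, c(i0, i1, i2, i3))) {
    p <- pts[i, ]
    vis <- which(vapply(faces, function(f) sum(f$n * p) - f$off > eps, TRUE))
    if (!length(vis)) next
    edges <- do.call(rbind, lapply(faces[vis], function(f)
      rbind(f$v[1:2], f$v[2:3], f$v[c(3, 1)])))
    faces <- faces[-vis]
    for (e in seq_len(nrow(edges))) {
      rev_match <- which(edges[, 1] == edges[e, 2] & edges[, 2] == edges[e, 1])
      if (length(rev_match)) next
      faces[[length(faces) + 1L]] <- face(edges[e, 1], edges[e, 2], i)
    }
  }
  list(faces = faces, O = O)
}

oracle_hull_volume <- function(pts) {
  h <- oracle_hull_faces(pts)
  sum(vapply(h$faces, function(f) {
    a <- pts[f$v[1], ]; b <- pts[f$v[2], ]; c <- pts[f$v[3], ]
    # tetra (O, a, b, c) with outward orientation
    abs(det(rbind(a - h$O, b - h$O, c - h$O))) / 6
  }, numeric(1)))
}

# Monte-Carlo hull volume: rejection sampling in the bounding box against the
# half-space representation from the R hull. For large clouds the hull is
# built on the exact extreme subset (support points over many directions,
# plus everything not provably interior to their hull).
oracle_mc_hull_volume <- function(pts, n_samples = 1e6, seed = 1) {
  set.seed(seed)
  if (nrow(pts) > 400) {
    dirs <- matrix(stats::rnorm(3 * 500), ncol = 3)
    sup <- unique(apply(pts %*% t(dirs), 2, which.max))
    h0 <- oracle_hull_faces(pts[sup, , drop = FALSE])
    nmat <- t(vapply(h0$faces, function(f) f$n, numeric(3)))
    offs <- vapply(h0$faces, function(f) f$off, numeric(1))
    sd_all <- pts %*% t(nmat)
    margin <- sweep(sd_all, 2, offs)
    keep <- which(apply(margin, 1, max) > -1e-9)
    pts <- pts[unique(c(sup, keep)), , drop = FALSE]
  }
  h <- oracle_hull_faces(pts)
  nmat <- t(vapply(h$faces, function(f) f$n, numeric(3)))
  offs <- vapply(h$faces, function(f) f$off, numeric(1))
  lo <- apply(pts, 2, min)
  hi <- apply(pts, 2, max)
  vol_box <- prod(hi - lo)
  n_in <- 0
  done <- 0
  chunk <- 50000L
  while (done < n_samples) {
    m <- min(chunk, n_samples - done)
    q <- cbind(stats::runif(m, lo[1], hi[1]), stats::runif(m, lo[2], hi[2]),
               stats::runif(m, lo[3], hi[3]))
    sd <- q %*% t(nmat)
    inside <- rowSums(sweep(sd, 2, offs) <= 1e-12) == ncol(sd)
    n_in <- n_in + sum(inside)
    done <- done + m
  }
  vol_box * n_in / n_samples
}
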