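#' Set-abstraction (encoder) layer configuration
#'
#' One encoder stage: farthest-point sampling of `n_centroids` centroids,
#' multi-scale radius grouping, and a shared per-point MLP with max-pooling
#' per group. Features gathered at the different radii are concatenated
#' (multi-scale grouping).
#'
#' @param n_centroids number of centroids sampled by FPS.
#' @param radii grouping radii in cm, strictly increasing; `Inf` groups all
#'   points (the global layer).
#' @param n_samples per-radius cap on gathered neighbors (`NA` with an
#'   infinite radius means "all points").
#' @param mlp_channels list (one integer vector per radius) of per-point
#'   feature widths.
#' @return an `sa_layer_config` list.
#' @export
sa_layer_config <- function(n_centroids, radii, n_samples, mlp_channels) {
  if (!is.list(mlp_channels)) mlp_channels <- list(mlp_channels)
  if (length(radii) != length(n_samples) ||
      length(radii) != length(mlp_channels))
    stop("radii, n_samples and mlp_channels must have equal length")
  if (length(radii) > 1 && any(diff(radii) <= 0))
    stop("radii must be strictly increasing")
  if (n_centroids < 1) stop("n_centroids must be >= 1")
  structure(list(n_centroids = as.integer(n_centroids), radii = radii,
                 n_samples = n_samples,
                 mlp_channels = lapply(mlp_channels, as.integer)),
            class = "sa_layer_config")
}

#' Interpolate-and-PointNet (decoder) layer configuration
#'
#' One decoder stage: inverse-distance-squared k-NN interpolation of the
#' coarser level's features onto the finer positions, concatenation with the
#' matching encoder skip features, then a shared MLP.
#'
#' @param mlp_channels integer vector of feature widths after the skip
#'   concatenation.
#' @param k_interp neighbor count for the interpolation (default 3).
#' @return an `ip_layer_config` list.
#' @export
ip_layer_config <- function(mlp_channels, k_interp = 3L) {
  if (k_interp < 1) stop("k_interp must be >= 1")
  structure(list(k_interp = as.integer(k_interp),
                 mlp_channels = as.integer(mlp_channels)),
            class = "ip_layer_config")
}

#' Network configuration (3 SA + 3 IP layers)
#'
#' @param sa_layers list of exactly 3 [sa_layer_config()].
#' @param ip_layers list of exactly 3 [ip_layer_config()] (applied coarse to
#'   fine).
#' @param n_classes number of output classes (2: branch top vs remainder).
#' @param head_channels width of the final shared fully connected layer.
#' @param dropout dropout probability before the classification layer
#'   (training only).
#' @return a `network_config` list.
#' @export
network_config <- function(sa_layers, ip_layers, n_classes = 2L,
                           head_channels = 128L, dropout = 0.5) {
  if (length(sa_layers) != 3 || length(ip_layers) != 3)
    stop("exactly 3 SA and 3 IP layers are required")
  structure(list(sa_layers = sa_layers, ip_layers = ip_layers,
                 n_classes = as.integer(n_classes),
                 head_channels = as.integer(head_channels), dropout = dropout),
            class = "network_config")
}

#' Default (full-size) architecture
#'
#' The canonical multi-scale-grouping segmentation configuration for clouds
#' of a few thousand points; all widths are overridable by constructing a
#' [network_config()] directly.
#' @return a [network_config()].
#' @export
default_network_config <- function() {
  network_config(
    sa_layers = list(
      sa_layer_config(1024, c(1, 2, 4), c(16, 32, 64),
                      list(c(32, 32, 64), c(64, 64, 128), c(64, 96, 128))),
      sa_layer_config(256, c(4, 8), c(16, 32),
                      list(c(128, 128, 256), c(128, 196, 256))),
      sa_layer_config(1, Inf, NA, list(c(256, 512, 1024)))
    ),
    ip_layers = list(
      ip_layer_config(c(256, 256)),
      ip_layer_config(c(256, 128)),
      ip_layer_config(c(128, 128, 128))
    )
  )
}

#' Reduced architecture for desk-scale experiments
#'
#' Centroid counts 128/32/8 with correspondingly narrow MLPs; trains on a
#' CPU in minutes. Radii are in cm and sized for ~30-50 cm tassels sampled
#' at ~1000 points.
#' @param dropout dropout probability (default 0.5).
#' @return a [network_config()].
#' @export
reduced_network_config <- function(dropout = 0.5) {
  network_config(
    sa_layers = list(
      sa_layer_config(128, c(2, 4), c(16, 32),
                      list(c(16, 16, 32), c(32, 32, 64))),
      sa_layer_config(32, c(8, 16), c(8, 16),
                      list(c(64, 64, 96), c(64, 64, 96))),
      sa_layer_config(8, Inf, NA, list(c(128, 128, 256)))
    ),
    ip_layers = list(
      ip_layer_config(c(128, 128)),
      ip_layer_config(c(128, 96)),
      ip_layer_config(c(96, 64))
    ),
    head_channels = 64L,
    dropout = dropout
  )
}

#' Training hyperparameters
#'
#' Defaults follow the published recipe: batch size 24, initial learning
#' rate 0.001 halved every 20 epochs, Adam with first-moment coefficient
#' (momentum) 0.9 and weight decay 0.0001; training stops early once the
#' epoch loss falls below `loss_threshold`.
#'
#' @param batch_size clouds per optimizer step.
#' @param lr0 initial learning rate.
#' @param lr_halving_period epochs between halvings of the learning rate.
#' @param epochs maximum number of epochs.
#' @param weight_decay L2 coefficient added to the gradient.
#' @param momentum Adam first-moment coefficient (beta1).
#' @param loss_threshold early-stop threshold on the epoch training loss.
#' @param seed RNG seed controlling init order, shuffling and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 24L, lr0 = 0.001,
                         lr_halving_period = 20L, epochs = 50L,
                         weight_decay = 1e-4, momentum = 0.9,
                         loss_threshold = 0.001, seed = 1L) {
  stopifnot(batch_size >= 1, lr0 > 0, lr_halving_period >= 1, epochs >= 1,
            weight_decay >= 0, momentum > 0, momentum < 1)
  structure(list(batch_size = as.integer(batch_size), lr0 = lr0,
                 lr_halving_period = as.integer(lr_halving_period),
                 epochs = as.integer(epochs), weight_decay = weight_decay,
                 momentum = momentum, loss_threshold = loss_threshold,
                 seed = as.integer(seed)),
            class = "train_config")
}

# --- parameter initialization ----------------------------------------------

he_mat <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out)
}

new_mlp <- function(c_in, widths) {
  lapply(seq_along(widths), function(d) {
    fi <- if (d == 1) c_in else widths[d - 1]
    list(W = he_mat(fi, widths[d]), b = rep(0, widths[d]))
  })
}

#' Initialize a tip-segmentation model
#'
#' @param config a [network_config()].
#' @param seed RNG seed for the (He) weight initialization.
#' @param in_channels input feature channels besides coordinates (3:
#'   normals).
#' @return a `tipnet_model` (configuration plus parameter tree).
#' @export
init_tipnet <- function(config = default_network_config(), seed = 1L,
                        in_channels = 3L) {
  withr_seed(seed, {
    c_prev <- in_channels
    sa <- vector("list", 3)
    skip_channels <- integer(4)
    skip_channels[1] <- c_prev
    for (l in 1:3) {
      cfg <- config$sa_layers[[l]]
      branches <- lapply(seq_along(cfg$radii), function(j)
        new_mlp(3L + c_prev, cfg$mlp_channels[[j]]))
      sa[[l]] <- branches
      c_prev <- sum(vapply(cfg$mlp_channels, function(w) w[length(w)], 1L))
      skip_channels[l + 1] <- c_prev
    }
    ip <- vector("list", 3)
    c_coarse <- skip_channels[4]
    for (l in 1:3) { # l = 1 maps level 3 -> 2, l = 3 maps level 1 -> 0
      fine_level <- 3 - l
      cfg <- config$ip_layers[[l]]
      ip[[l]] <- new_mlp(c_coarse + skip_channels[fine_level + 1],
                         cfg$mlp_channels)
      c_coarse <- cfg$mlp_channels[length(cfg$mlp_channels)]
    }
    head <- list(
      W1 = he_mat(c_coarse, config$head_channels), b1 = rep(0, config$head_channels),
      W2 = he_mat(config$head_channels, config$n_classes),
      b2 = rep(0, config$n_classes)
    )
    structure(list(config = config, params = list(sa = sa, ip = ip, head = head),
                   in_channels = as.integer(in_channels)),
              class = "tipnet_model")
  })
}

# --- per-cloud geometry plan -----------------------------------------------

# All neighborhood structure depends only on coordinates, so it is computed
# once per cloud and reused across epochs.
build_plan <- function(config, coords) {
  lv_coords <- list(coords)
  sa_plans <- vector("list", 3)
  for (l in 1:3) {
    cfg <- config$sa_layers[[l]]
    prev <- lv_coords[[l]]
    cent_idx <- .fps_cpp(prev, min(cfg$n_centroids, nrow(prev)), 1L)
    cent <- prev[cent_idx, , drop = FALSE]
    branches <- vector("list", length(cfg$radii))
    for (j in seq_along(cfg$radii)) {
      S <- cfg$n_samples[j]
      if (is.na(S) || !is.finite(cfg$radii[j])) S <- nrow(prev)
      S <- min(S, nrow(prev))
      grp <- .ball_query_cpp(prev, cent, as.integer(cent_idx), cfg$radii[j],
                             as.integer(S))
      flat <- as.vector(t(grp)) # rows of one group contiguous
      rel <- prev[flat, , drop = FALSE] -
        cent[rep(seq_len(nrow(cent)), each = S), , drop = FALSE]
      branches[[j]] <- list(flat = flat, rel = rel, S = S)
    }
    sa_plans[[l]] <- list(cent_idx = as.integer(cent_idx), branches = branches)
    lv_coords[[l + 1]] <- cent
  }
  ip_plans <- vector("list", 3)
  for (l in 1:3) {
    fine_level <- 3 - l
    queries <- lv_coords[[fine_level + 1]]
    supports <- lv_coords[[fine_level + 2]]
    k <- min(config$ip_layers[[l]]$k_interp, nrow(supports))
    nn <- .knn_query_cpp(queries, supports, k)
    w <- interp_weights(nn$dist)
    ip_plans[[l]] <- list(idx = nn$idx, w = w, n_support = nrow(supports))
  }
  list(lv_coords = lv_coords, sa = sa_plans, ip = ip_plans,
       n = nrow(coords))
}

# normalized inverse-distance-squared weights; exact rows for coincident
# supports (d = 0 dominates)
interp_weights <- function(dist) {
  zero <- dist == 0
  anyz <- rowSums(zero) > 0
  w <- 1 / pmax(dist, 1e-300)^2
  if (any(anyz)) {
    w[anyz, ] <- 0
    first0 <- max.col(zero[anyz, , drop = FALSE] * 1, ties.method = "first")
    w[cbind(which(anyz), first0)] <- 1
  }
  w / rowSums(w)
}

# --- forward / backward -----------------------------------------------------

relu <- function(x) (x > 0) * x

mlp_forward <- function(mlp, X) {
  acts <- vector("list", length(mlp) + 1)
  acts[[1]] <- X
  for (d in seq_along(mlp)) {
    Z <- acts[[d]] %*% mlp[[d]]$W
    Z <- sweep(Z, 2, mlp[[d]]$b, `+`)
    acts[[d + 1]] <- relu(Z)
  }
  acts
}

mlp_backward <- function(mlp, acts, dOut) {
  grads <- vector("list", length(mlp))
  d <- dOut
  for (k in rev(seq_along(mlp))) {
    d <- d * (acts[[k + 1]] > 0)
    grads[[k]] <- list(W = crossprod(acts[[k]], d), b = colSums(d))
    if (k > 1) d <- d %*% t(mlp[[k]]$W)
  }
  list(grads = grads, dX = d %*% t(mlp[[1]]$W))
}

gather_interp <- function(plan_ip, coarse_feats) {
  out <- matrix(0, nrow(plan_ip$idx), ncol(coarse_feats))
  for (j in seq_len(ncol(plan_ip$idx)))
    out <- out + plan_ip$w[, j] * coarse_feats[plan_ip$idx[, j], , drop = FALSE]
  out
}

scatter_interp <- function(plan_ip, dFine, n_support, n_ch) {
  out <- matrix(0, n_support, n_ch)
  for (j in seq_len(ncol(plan_ip$idx))) {
    contrib <- rowsum(plan_ip$w[, j] * dFine, group = plan_ip$idx[, j])
    rows <- as.integer(rownames(contrib))
    out[rows, ] <- out[rows, ] + contrib
  }
  out
}

tipnet_forward_full <- function(model, plan, feats0, dropout_mask = NULL) {
  cfg <- model$config
  p <- model$params
  enc <- vector("list", 4)
  enc[[1]] <- feats0
  enc_cache <- vector("list", 3)
  for (l in 1:3) {
    spl <- plan$sa[[l]]
    pooled <- NULL
    bcache <- vector("list", length(spl$branches))
    for (j in seq_along(spl$branches)) {
      br <- spl$branches[[j]]
      X <- cbind(br$rel, enc[[l]][br$flat, , drop = FALSE])
      acts <- mlp_forward(p$sa[[l]][[j]], X)
      gm <- .group_max_cpp(acts[[length(acts)]], br$S)
      bcache[[j]] <- list(acts = acts, argmax = gm$argmax)
      pooled <- if (is.null(pooled)) gm$max else cbind(pooled, gm$max)
    }
    enc_cache[[l]] <- bcache
    enc[[l + 1]] <- pooled
  }
  f <- enc[[4]]
  dec_cache <- vector("list", 3)
  for (l in 1:3) {
    fine_level <- 3 - l
    fi <- gather_interp(plan$ip[[l]], f)
    X <- cbind(fi, enc[[fine_level + 1]])
    acts <- mlp_forward(p$ip[[l]], X)
    dec_cache[[l]] <- list(acts = acts, c_interp = ncol(fi))
    f <- acts[[length(acts)]]
  }
  H <- relu(sweep(f %*% p$head$W1, 2, p$head$b1, `+`))
  Hd <- if (is.null(dropout_mask)) H else H * dropout_mask
  logits <- sweep(Hd %*% p$head$W2, 2, p$head$b2, `+`)
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  prob <- e / rowSums(e)
  list(prob = prob, logits = logits, H = H, Hd = Hd, enc = enc,
       enc_cache = enc_cache, dec_cache = dec_cache)
}

tipnet_backward_full <- function(model, plan, cache, labels,
                                 dropout_mask = NULL) {
  p <- model$params
  n <- nrow(cache$prob)
  dlogits <- cache$prob
  dlogits[cbind(seq_len(n), labels + 1L)] <-
    dlogits[cbind(seq_len(n), labels + 1L)] - 1
  dlogits <- dlogits / n

  gW2 <- crossprod(cache$Hd, dlogits)
  gb2 <- colSums(dlogits)
  dHd <- dlogits %*% t(p$head$W2)
  dH <- if (is.null(dropout_mask)) dHd else dHd * dropout_mask
  dH <- dH * (cache$H > 0)
  f_last <- cache$dec_cache[[3]]$acts[[length(cache$dec_cache[[3]]$acts)]]
  # field order must mirror params$head: tree arithmetic pairs by position
  g_head <- list(W1 = crossprod(f_last, dH), b1 = colSums(dH),
                 W2 = gW2, b2 = gb2)
  df <- dH %*% t(p$head$W1)

  d_enc <- vector("list", 4)
  g_ip <- vector("list", 3)
  for (l in 3:1) {
    fine_level <- 3 - l
    bk <- mlp_backward(p$ip[[l]], cache$dec_cache[[l]]$acts, df)
    g_ip[[l]] <- bk$grads
    ci <- cache$dec_cache[[l]]$c_interp
    d_interp <- bk$dX[, seq_len(ci), drop = FALSE]
    d_skip <- bk$dX[, -seq_len(ci), drop = FALSE]
    d_enc[[fine_level + 1]] <- add_or_init(d_enc[[fine_level + 1]], d_skip)
    d_coarse <- scatter_interp(plan$ip[[l]], d_interp,
                               plan$ip[[l]]$n_support, ci)
    if (l == 1) d_enc[[4]] <- add_or_init(d_enc[[4]], d_coarse)
    else df <- d_coarse # becomes the output gradient of IP layer l - 1
  }

  g_sa <- vector("list", 3)
  for (l in 3:1) {
    spl <- plan$sa[[l]]
    dpooled <- d_enc[[l + 1]]
    off <- 0L
    g_sa[[l]] <- vector("list", length(spl$branches))
    for (j in seq_along(spl$branches)) {
      br <- spl$branches[[j]]
      acts <- cache$enc_cache[[l]][[j]]$acts
      cj <- ncol(acts[[length(acts)]])
      dslice <- dpooled[, (off + 1):(off + cj), drop = FALSE]
      off <- off + cj
      dlast <- matrix(0, nrow(acts[[length(acts)]]), cj)
      am <- cache$enc_cache[[l]][[j]]$argmax
      for (cc in seq_len(cj)) dlast[cbind(am[, cc], cc)] <- dslice[, cc]
      bk <- mlp_backward(p$sa[[l]][[j]], acts, dlast)
      g_sa[[l]][[j]] <- bk$grads
      d_feats <- bk$dX[, -(1:3), drop = FALSE]
      contrib <- rowsum(d_feats, group = br$flat)
      rows <- as.integer(rownames(contrib))
      if (is.null(d_enc[[l]]))
        d_enc[[l]] <- matrix(0, nrow(plan$lv_coords[[l]]), ncol(d_feats))
      d_enc[[l]][rows, ] <- d_enc[[l]][rows, ] + contrib
    }
  }
  list(sa = g_sa, ip = g_ip, head = g_head)
}

add_or_init <- function(acc, x) if (is.null(acc)) x else acc + x

# --- generic parameter-tree arithmetic --------------------------------------

# elementwise map over a nested list of numeric leaves (two trees must share
# the same shape)
tree_map_num <- function(f, a, b = NULL) {
  if (is.numeric(a)) return(if (is.null(b)) f(a) else f(a, b))
  out <- vector("list", length(a))
  names(out) <- names(a)
  for (i in seq_along(a))
    out[[i]] <- if (is.null(b)) tree_map_num(f, a[[i]])
      else tree_map_num(f, a[[i]], b[[i]])
  out
}

#' Train the tip-segmentation network
#'
#' Optimizes the softmax cross-entropy with Adam under the configured
#' learning-rate schedule (`lr0 * 0.5^floor(epoch / halving_period)`),
#' weight decay and dropout. Geometry plans (FPS, grouping, interpolation
#' neighborhoods) are computed once per cloud. Deterministic for a fixed
#' `config$seed`.
#'
#' @param model a [init_tipnet()] model.
#' @param train_set list of labeled [point_cloud()]s with normals (estimated
#'   with k = 16 when absent).
#' @param val_set optional list of labeled clouds evaluated each epoch.
#' @param config a [train_config()].
#' @return list with the trained `model` and a `history` data frame
#'   (epoch, lr, loss, accuracy, and validation columns when `val_set`
#'   is given).
#' @export
train_tipnet <- function(model, train_set, val_set = NULL,
                         config = train_config()) {
  if (!length(train_set)) stop("empty training set")
  for (cl in train_set)
    if (is.null(cl$labels)) stop("every training cloud needs labels")
  train_set <- lapply(train_set, function(cl)
    if (is.null(cl$normals)) estimate_normals(cl, 16L) else cl)
  plans <- lapply(train_set, function(cl) build_plan(model$config, cl$coords))
  feats <- lapply(train_set, function(cl) cl$normals)
  labels <- lapply(train_set, function(cl) as.integer(cl$labels))

  params <- model$params
  mstate <- tree_map_num(function(x) x * 0, params)
  vstate <- tree_map_num(function(x) x * 0, params)
  beta1 <- config$momentum
  beta2 <- 0.999
  epsa <- 1e-8
  t_step <- 0L
  history <- data.frame()
  nclouds <- length(train_set)

  withr_seed(config$seed, {
    for (epoch in seq_len(config$epochs) - 1L) {
      lr <- config$lr0 * 0.5^(epoch %/% config$lr_halving_period)
      order <- sample.int(nclouds)
      batches <- split(order, ceiling(seq_along(order) / config$batch_size))
      ep_loss <- 0
      ep_correct <- 0
      ep_points <- 0
      for (batch in batches) {
        gacc <- NULL
        bloss <- 0
        for (ci in batch) {
          mdl <- list(config = model$config, params = params)
          mask <- NULL
          if (model$config$dropout > 0) {
            keep <- 1 - model$config$dropout
            mask <- matrix(
              (stats::runif(plans[[ci]]$n * model$config$head_channels) < keep) / keep,
              plans[[ci]]$n, model$config$head_channels)
          }
          fwd <- tipnet_forward_full(mdl, plans[[ci]], feats[[ci]], mask)
          loss <- cross_entropy_loss(fwd$prob, labels[[ci]])
          pred <- max.col(fwd$prob, ties.method = "first") - 1L
          pred[fwd$prob[, 1] == fwd$prob[, 2]] <- 0L
          ep_correct <- ep_correct + sum(pred == labels[[ci]])
          ep_points <- ep_points + length(labels[[ci]])
          bloss <- bloss + loss
          g <- tipnet_backward_full(mdl, plans[[ci]], fwd, labels[[ci]], mask)
          gacc <- if (is.null(gacc)) g
            else tree_map_num(`+`, gacc, g)
        }
        nb <- length(batch)
        gacc <- tree_map_num(function(x) x / nb, gacc)
        if (config$weight_decay > 0)
          gacc <- tree_map_num(function(g, w) g + config$weight_decay * w,
                               gacc, params)
        t_step <- t_step + 1L
        mstate <- tree_map_num(function(m, g) beta1 * m + (1 - beta1) * g,
                               mstate, gacc)
        vstate <- tree_map_num(function(v, g) beta2 * v + (1 - beta2) * g^2,
                               vstate, gacc)
        bc1 <- 1 - beta1^t_step
        bc2 <- 1 - beta2^t_step
        upd <- tree_map_num(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + epsa),
                            mstate, vstate)
        params <- tree_map_num(`-`, params, upd)
        ep_loss <- ep_loss + bloss
      }
      row <- data.frame(epoch = epoch, lr = lr, loss = ep_loss / nclouds,
                        accuracy = ep_correct / ep_points)
      if (!is.null(val_set)) {
        vstats <- evaluate_tipnet(list(config = model$config, params = params),
                                  val_set)
        row$val_loss <- vstats$loss
        row$val_accuracy <- vstats$accuracy
      }
      history <- rbind(history, row)
      if (row$loss < config$loss_threshold) break
    }
  })
  model$params <- params
  list(model = model, history = history)
}

evaluate_tipnet <- function(model, clouds) {
  loss <- 0
  correct <- 0
  npts <- 0
  for (cl in clouds) {
    if (is.null(cl$normals)) cl <- estimate_normals(cl, 16L)
    plan <- build_plan(model$config, cl$coords)
    fwd <- tipnet_forward_full(model, plan, cl$normals, NULL)
    loss <- loss + cross_entropy_loss(fwd$prob, as.integer(cl$labels))
    pred <- as.integer(fwd$prob[, 2] > fwd$prob[, 1])
    correct <- correct + sum(pred == cl$labels)
    npts <- npts + length(cl$labels)
  }
  list(loss = loss / length(clouds), accuracy = correct / npts)
}

#' Forward pass: per-point class probabilities
#'
#' @param model a `tipnet_model`.
#' @param cloud a [point_cloud()] with normals (6 input channels overall).
#' @return `N x n_classes` matrix; rows are nonnegative and sum to 1.
#' @export
tipnet_forward <- function(model, cloud) {
  if (is.null(cloud$normals)) stop("cloud has no normals channel")
  plan <- build_plan(model$config, cloud$coords)
  tipnet_forward_full(model, plan, cloud$normals, NULL)$prob
}

#' Predict branch-tip labels
#'
#' Labels each point with the argmax class of [tipnet_forward()]; exact ties
#' resolve to class 0 (remainder). Normals are estimated with k = 16 when
#' missing.
#'
#' @param model a trained `tipnet_model`.
#' @param cloud a [point_cloud()].
#' @return the cloud with a binary `labels` channel (1 = branch top).
#' @export
predict_tips <- function(model, cloud) {
  if (is.null(cloud$normals)) cloud <- estimate_normals(cloud, 16L)
  prob <- tipnet_forward(model, cloud)
  cloud$labels <- as.integer(prob[, 2] > prob[, 1])
  attr(cloud, "tip_prob") <- prob
  cloud
}

#' Inverse-distance-squared k-NN feature interpolation
#'
#' Each query receives the weighted mean of its `k_interp` nearest support
#' features with weights `1 / d^2`; a query coinciding with a support takes
#' that support's feature exactly.
#'
#' @param queries `M x 3` positions.
#' @param supports `S x 3` positions (`S >= k_interp`).
#' @param support_features `S x C` feature matrix.
#' @param k_interp neighbor count.
#' @return `M x C` interpolated features.
#' @export
interpolate_features <- function(queries, supports, support_features,
                                 k_interp = 3L) {
  queries <- as_coord_matrix(queries)
  supports <- as_coord_matrix(supports)
  if (!is.matrix(support_features))
    support_features <- matrix(support_features, nrow = nrow(supports))
  if (nrow(supports) < 1) stop("empty supports")
  if (k_interp < 1 || k_interp > nrow(supports))
    stop("k_interp must lie in [1, number of supports]")
  nn <- .knn_query_cpp(queries, supports, as.integer(k_interp))
  w <- interp_weights(nn$dist)
  out <- matrix(0, nrow(queries), ncol(support_features))
  for (j in seq_len(k_interp))
    out <- out + w[, j] * support_features[nn$idx[, j], , drop = FALSE]
  out
}

#' Softmax cross-entropy loss
#'
#' Mean over points of the negative log predicted probability at the true
#' label, clamped at 1e-12.
#'
#' @param probabilities `N x n_classes` matrix of row-stochastic predictions.
#' @param labels integer vector of true labels in `[0, n_classes)`.
#' @return scalar loss.
#' @export
cross_entropy_loss <- function(probabilities, labels) {
  labels <- as.integer(labels)
  if (any(labels < 0) || any(labels >= ncol(probabilities)))
    stop("label out of range")
  if (length(labels) != nrow(probabilities))
    stop("labels length must match probability rows")
  q <- probabilities[cbind(seq_along(labels), labels + 1L)]
  mean(-log(pmax(q, 1e-12)))
}

#' Segmentation evaluation metrics
#'
#' Per-class IoU, accuracy, precision and recall from the confusion counts,
#' treating each class in turn as positive. An undefined ratio (0/0) is
#' reported as 1 when the class is absent from both prediction and truth,
#' else 0.
#'
#' @param pred,truth equal-length binary (or small-integer) label vectors.
#' @param classes classes to evaluate (default 0 and 1).
#' @return data frame with one row per class: `class, tp, fp, fn, tn, iou,
#'   accuracy, precision, recall`.
#' @export
segmentation_metrics <- function(pred, truth, classes = c(0L, 1L)) {
  if (length(pred) != length(truth)) stop("length mismatch")
  out <- lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    tn <- sum(pred != cl & truth != cl)
    absent <- (tp + fp) == 0 && (tp + fn) == 0
    ratio <- function(num, den) {
      if (den == 0) return(if (absent) 1 else 0)
      num / den
    }
    data.frame(class = cl, tp = tp, fp = fp, fn = fn, tn = tn,
               iou = ratio(tp, tp + fp + fn),
               accuracy = (tp + tn) / length(pred),
               precision = ratio(tp, tp + fp),
               recall = ratio(tp, tp + fn))
  })
  do.call(rbind, out)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is the package's own serialized parameter container plus
#' the [network_config()].
#'
#' @param model a `tipnet_model`.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored `tipnet_model` (load).
#' @export
save_tipnet <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_tipnet
#' @export
load_tipnet <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "tipnet_model")) stop("not a tipnet checkpoint")
  model
}
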