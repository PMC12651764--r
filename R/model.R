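# Point-cloud regression network of the PointNet family, implemented
# directly in base R matrix algebra: shared per-point dense layers, batch
# normalization and ReLU, a symmetric max-pooling aggregation into a global
# feature vector, a fully connected head, and a per-output bounded squashing
# transform that maps each of the 9 outputs (8 rubric criteria + total) into
# its rubric range. The max-pooling makes the output invariant to any
# permutation of input points. Batch normalization follows the canonical
# trunk; without it the pooled features vary across cases by a tiny fraction
# of their scale and gradient training stalls. Per-point layers normalize
# over all points of the batch; head layers over the batch; inference uses
# the running statistics, so a single cloud's prediction is a pure function
# of that cloud.

output_keys <- function() c(rubric_criteria()$key, "total")

output_bounds <- function() {
  r <- rubric_criteria()
  cbind(min = c(r$min, 0), max = c(r$max, rubric_max_total()))
}

#' Network configuration
#'
#' @param n_points number of input points the network consumes.
#' @param point_widths widths of the shared per-point layers.
#' @param head_widths widths of the fully connected head.
#' @param seed initialization seed.
#' @param batch_norm batch-normalize every hidden layer (canonical; needed
#'   for the pooled features to be well-conditioned).
#' @param bn_momentum running-statistics update rate.
#' @param bn_eps variance floor inside the normalization.
#' @param use_input_transform learned input alignment (T-Net); inputs are
#'   already pose-normalized to the unit sphere, so this stays off.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_points = 2048L,
                         point_widths = c(64L, 64L, 128L, 1024L),
                         head_widths = c(512L, 256L),
                         seed = 42L,
                         batch_norm = TRUE,
                         bn_momentum = 0.1,
                         bn_eps = 1e-5,
                         use_input_transform = FALSE) {
  stopifnot(all(point_widths >= 1), all(head_widths >= 1), n_points >= 1)
  if (isTRUE(use_input_transform))
    stop_named("prepscore_bad_config",
               "the learned input transform is not available; inputs are pose-normalized upstream")
  structure(list(n_points = as.integer(n_points),
                 point_widths = as.integer(point_widths),
                 head_widths = as.integer(head_widths),
                 n_outputs = length(output_keys()),
                 bounds = output_bounds(),
                 seed = as.integer(seed),
                 batch_norm = isTRUE(batch_norm),
                 bn_momentum = bn_momentum, bn_eps = bn_eps,
                 use_input_transform = FALSE),
            class = "model_config")
}

dense_init <- function(n_in, n_out) {
  list(W = matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       gamma = rep(1, n_out), beta = numeric(n_out))
}

#' Initialize network parameters
#'
#' Fan-in-scaled (He) Gaussian weights, unit-gain normalization layers;
#' deterministic in the config seed.
#'
#' @param config a [model_config()].
#' @return A list of named layers, class `model_params`.
#' @export
init_params <- function(config) {
  stopifnot(inherits(config, "model_config"))
  with_seed(config$seed, {
    widths <- c(3L, config$point_widths)
    point <- lapply(seq_len(length(widths) - 1L),
                    function(i) dense_init(widths[i], widths[i + 1L]))
    hw <- c(config$point_widths[length(config$point_widths)], config$head_widths)
    head <- lapply(seq_len(length(hw) - 1L),
                   function(i) dense_init(hw[i], hw[i + 1L]))
    out <- dense_init(hw[length(hw)], config$n_outputs)
    out$b <- out$beta
    out$gamma <- NULL
    out$beta <- NULL
    structure(list(point = point, head = head, out = out),
              class = "model_params")
  })
}

# Running normalization statistics; model state alongside the learnable
# parameters, updated by training-mode forward passes.
init_norms <- function(config) {
  mk <- function(w) list(rm = numeric(w), rv = rep(1, w))
  list(point = lapply(config$point_widths, mk),
       head = lapply(config$head_widths, mk))
}

n_parameters <- function(params) {
  sum(rapply(unclass(params), length, how = "unlist"))
}

squash <- function(x) plogis(x)

# Fast column-wise affine ops (sweep() spends most of its time in aperm).
col_add <- function(Z, v) Z + rep(v, each = nrow(Z))
col_mul <- function(Z, v) Z * rep(v, each = nrow(Z))

# Batch-norm forward over the rows of Z for one layer. Uses batch statistics
# when training with >= 2 rows (updating the running stats), otherwise the
# running statistics. Returns the cache backward() needs.
bn_forward <- function(Z, lay, norm, eps, momentum, training) {
  use_batch <- training && nrow(Z) >= 2L
  if (use_batch) {
    mu <- colMeans(Z)
    va <- colMeans(Z^2) - mu^2
    norm$rm <- (1 - momentum) * norm$rm + momentum * mu
    norm$rv <- (1 - momentum) * norm$rv + momentum * va
  } else {
    mu <- norm$rm
    va <- norm$rv
  }
  istd <- 1 / sqrt(pmax(va, 0) + eps)
  xhat <- col_mul(col_add(Z, -mu), istd)
  Y <- col_add(col_mul(xhat, lay$gamma), lay$beta)
  list(Y = Y, xhat = xhat, istd = istd, use_batch = use_batch, norm = norm)
}

bn_backward <- function(dY, cache, lay) {
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- col_mul(dY, lay$gamma)
  if (cache$use_batch) {
    t1 <- col_add(dxhat, -colMeans(dxhat))
    t2 <- col_mul(cache$xhat, colMeans(dxhat * cache$xhat))
    dZ <- col_mul(t1 - t2, cache$istd)
  } else {
    dZ <- col_mul(dxhat, cache$istd)
  }
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

as_cloud_matrix <- function(cloud, config, check = TRUE) {
  pts <- if (inherits(cloud, "point_cloud")) cloud$points else as.matrix(cloud)
  if (nrow(pts) != config$n_points)
    stop_named("prepscore_bad_input",
               sprintf("cloud has %d points; config expects %d",
                       nrow(pts), config$n_points))
  if (check) {
    ctr <- sqrt(sum(colMeans(pts)^2))
    if (ctr > 1e-4)
      warn_named("prepscore_unnormalized",
                 sprintf("input cloud does not look normalized (centroid norm %.3g)", ctr))
  }
  pts
}

# Row-wise batch norm for the transposed point stage (features x points).
bn_forward_t <- function(Z, lay, norm, eps, momentum, training) {
  use_batch <- training && ncol(Z) >= 2L
  if (use_batch) {
    mu <- rowMeans(Z)
    va <- rowMeans(Z^2) - mu^2
    norm$rm <- (1 - momentum) * norm$rm + momentum * mu
    norm$rv <- (1 - momentum) * norm$rv + momentum * va
  } else {
    mu <- norm$rm
    va <- norm$rv
  }
  istd <- 1 / sqrt(pmax(va, 0) + eps)
  xhat <- (Z - mu) * istd
  Y <- xhat * lay$gamma + lay$beta
  list(Y = Y, xhat = xhat, istd = istd, use_batch = use_batch, norm = norm)
}

bn_backward_t <- function(dY, cache, lay) {
  dgamma <- rowSums(dY * cache$xhat)
  dbeta <- rowSums(dY)
  dxhat <- dY * lay$gamma
  dZ <- if (cache$use_batch) {
    cache$istd * ((dxhat - rowMeans(dxhat)) -
                    cache$xhat * rowMeans(dxhat * cache$xhat))
  } else {
    cache$istd * dxhat
  }
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

# Full forward pass over a batch with caches for backprop. mats: list of
# n_points x 3 matrices. The point stage runs on the transposed stacked
# matrix (features x points, so per-feature stats and affine ops recycle
# without copies); the max-pool reduces each sample's column block to one
# global feature row.
forward_full <- function(mats, params, config, norms, training = FALSE) {
  B <- length(mats)
  n <- config$n_points
  X <- t(do.call(rbind, mats))
  H <- vector("list", length(params$point) + 1L)
  caches <- vector("list", length(params$point))
  H[[1L]] <- X
  for (l in seq_along(params$point)) {
    lay <- params$point[[l]]
    Z <- crossprod(lay$W, H[[l]])
    if (config$batch_norm) {
      cb <- bn_forward_t(Z, lay, norms$point[[l]], config$bn_eps,
                         config$bn_momentum, training)
      norms$point[[l]] <- cb$norm
      caches[[l]] <- cb
      Z <- cb$Y
    } else {
      Z <- Z + lay$beta
    }
    H[[l + 1L]] <- pmax(Z, 0)
  }
  w_last <- config$point_widths[length(config$point_widths)]
  Hl <- H[[length(H)]]
  G <- matrix(0, B, w_last)
  pool_idx <- matrix(0L, B, w_last)
  for (b in seq_len(B)) {
    cols <- ((b - 1L) * n + 1L):(b * n)
    blk <- Hl[, cols, drop = FALSE]
    idx <- max.col(blk, ties.method = "first")
    pool_idx[b, ] <- (b - 1L) * n + idx
    G[b, ] <- blk[cbind(seq_len(w_last), idx)]
  }
  A <- vector("list", length(params$head) + 1L)
  hcaches <- vector("list", length(params$head))
  A[[1L]] <- G
  for (l in seq_along(params$head)) {
    lay <- params$head[[l]]
    Z <- A[[l]] %*% lay$W
    if (config$batch_norm) {
      cb <- bn_forward(Z, lay, norms$head[[l]], config$bn_eps,
                       config$bn_momentum, training)
      norms$head[[l]] <- cb$norm
      hcaches[[l]] <- cb
      Z <- cb$Y
    } else {
      Z <- col_add(Z, lay$beta)
    }
    A[[l + 1L]] <- pmax(Z, 0)
  }
  raw <- col_add(A[[length(A)]] %*% params$out$W, params$out$b)
  s <- squash(raw)
  lo <- config$bounds[, "min"]
  hi <- config$bounds[, "max"]
  Y <- col_add(col_mul(s, hi - lo), lo)
  colnames(Y) <- output_keys()
  list(Y = Y, s = s, H = H, A = A, caches = caches, hcaches = hcaches,
       pool_idx = pool_idx, norms = norms)
}

# Gradients of all learnable parameters given dY = dL/dY (batch x outputs).
backward_full <- function(params, config, fwd, dY) {
  lo <- config$bounds[, "min"]
  hi <- config$bounds[, "max"]
  s <- fwd$s
  d_raw <- dY * col_mul(s * (1 - s), hi - lo)
  A <- fwd$A
  g_out <- list(W = crossprod(A[[length(A)]], d_raw), b = colSums(d_raw))
  dA <- d_raw %*% t(params$out$W)
  g_head <- vector("list", length(params$head))
  for (l in rev(seq_along(params$head))) {
    dZ <- dA * (A[[l + 1L]] > 0)
    if (config$batch_norm) {
      bb <- bn_backward(dZ, fwd$hcaches[[l]], params$head[[l]])
      g_head[[l]] <- list(W = crossprod(A[[l]], bb$dZ),
                          gamma = bb$dgamma, beta = bb$dbeta)
      dA <- bb$dZ %*% t(params$head[[l]]$W)
    } else {
      g_head[[l]] <- list(W = crossprod(A[[l]], dZ),
                          gamma = numeric(length(params$head[[l]]$gamma)),
                          beta = colSums(dZ))
      dA <- dZ %*% t(params$head[[l]]$W)
    }
  }
  # scatter the pooled-feature gradient back to the argmax columns
  Hl <- fwd$H[[length(fwd$H)]]
  dH <- matrix(0, nrow(Hl), ncol(Hl))
  w_last <- nrow(Hl)
  for (b in seq_len(nrow(dY)))
    dH[cbind(seq_len(w_last), fwd$pool_idx[b, ])] <-
      dH[cbind(seq_len(w_last), fwd$pool_idx[b, ])] + dA[b, ]
  g_point <- vector("list", length(params$point))
  for (l in rev(seq_along(params$point))) {
    dZ <- dH * (fwd$H[[l + 1L]] > 0)
    if (config$batch_norm) {
      bb <- bn_backward_t(dZ, fwd$caches[[l]], params$point[[l]])
      g_point[[l]] <- list(W = tcrossprod(fwd$H[[l]], bb$dZ),
                           gamma = bb$dgamma, beta = bb$dbeta)
      if (l > 1L) dH <- params$point[[l]]$W %*% bb$dZ
    } else {
      g_point[[l]] <- list(W = tcrossprod(fwd$H[[l]], dZ),
                           gamma = numeric(length(params$point[[l]]$gamma)),
                           beta = rowSums(dZ))
      if (l > 1L) dH <- params$point[[l]]$W %*% dZ
    }
  }
  structure(list(point = g_point, head = g_head, out = g_out),
            class = "model_params")
}

#' Forward pass: point cloud(s) to bounded score vector(s)
#'
#' Inference mode: normalization layers use their running statistics, so each
#' cloud's output is a pure function of that cloud and the parameters.
#'
#' @param clouds a `point_cloud` (or bare n x 3 matrix), or a list of them.
#' @param params [init_params()] output (or trained parameters).
#' @param config the matching [model_config()].
#' @param norms running normalization statistics as trained; fresh (unit)
#'   statistics when `NULL`.
#' @return A matrix with one row per cloud and one column per output
#'   (rubric criteria in [rubric_criteria()] order, then `total`), each value
#'   inside its rubric bounds.
#' @export
forward <- function(clouds, params, config, norms = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(config, "model_config"))
  if (inherits(clouds, "point_cloud") || is.matrix(clouds)) clouds <- list(clouds)
  mats <- lapply(clouds, as_cloud_matrix, config = config)
  forward_full(mats, params, config, norms %||% init_norms(config),
               training = FALSE)$Y
}

#' Predict a score sheet for one preprocessed cloud
#'
#' Places the 8 criterion outputs into a [score_sheet()] and reports both the
#' network's direct total output (`total_head`) and the sum-of-criteria total
#' computed through [total_score()]; the two need not coincide, mirroring a
#' jointly trained separate total output.
#'
#' @param cloud a normalized `point_cloud`.
#' @param params trained `model_params`.
#' @param config the matching [model_config()].
#' @param norms running normalization statistics as trained.
#' @return A list of class `predicted_sheet`: `sheet`, `total_head`,
#'   `criteria_total`.
#' @export
predict_sheet <- function(cloud, params, config, norms = NULL) {
  y <- forward(cloud, params, config, norms)[1L, ]
  keys <- rubric_criteria()$key
  sheet <- score_sheet(if (inherits(cloud, "point_cloud"))
    cloud$provenance$source_id else "cloud",
    y[keys], pulp_exposure = FALSE, examiner = FALSE)
  structure(list(sheet = sheet,
                 total_head = unname(y[["total"]]),
                 criteria_total = total_score(sheet)),
            class = "predicted_sheet")
}

#' @export
print.predicted_sheet <- function(x, ...) {
  print(x$sheet)
  cat(sprintf("total (direct output): %.3f\n", x$total_head))
  invisible(x)
}
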