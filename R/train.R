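# Supervised training: mean-absolute-error in rubric points, block-wise
# epochs with a fresh optimizer per block, per-epoch checkpointing and
# best-epoch restore. Deterministic for fixed seeds on a fixed platform
# (single-threaded BLAS); determinism is a platform contract, not a
# cross-platform bit-exactness guarantee.

#' Training target vector of a score sheet
#'
#' The 9 regression targets: criterion values in [rubric_criteria()] order
#' followed by the rubric total.
#'
#' @param sheet a [score_sheet()].
#' @return Named numeric vector of length 9.
#' @export
sheet_to_target <- function(sheet) {
  c(sheet$values, total = total_score(sheet))
}

#' Mean absolute error loss in rubric points
#'
#' Weighted mean over the 9 outputs of the per-output mean absolute
#' difference. With uniform weights, a single case whose total differs by
#' `d` while all criteria agree contributes `d/9`.
#'
#' @param pred,ref numeric matrices (cases x outputs) or vectors.
#' @param weights optional per-output weights; uniform when `NULL`.
#' @return Scalar loss (rubric points).
#' @export
mae_loss <- function(pred, ref, weights = NULL) {
  pred <- rbind(pred)
  ref <- rbind(ref)
  if (!all(dim(pred) == dim(ref)))
    stop_named("prepscore_shape", "prediction and reference shapes differ")
  w <- weights %||% rep(1, ncol(pred))
  if (length(w) != ncol(pred))
    stop_named("prepscore_shape", "weights length must equal the output count")
  per_output <- colMeans(abs(pred - ref))
  sum(w * per_output) / sum(w)
}

# --- Adam optimizer on the nested parameter tree ------------------------

tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.numeric(trees[[1L]])) return(do.call(f, trees))
  out <- lapply(seq_along(trees[[1L]]), function(i)
    do.call(tree_map, c(list(f), lapply(trees, `[[`, i))))
  names(out) <- names(trees[[1L]])
  attributes(out) <- attributes(trees[[1L]])
  out
}

adam_init <- function(params) {
  zero <- tree_map(function(x) x * 0, unclass(params))
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, unclass(grads))
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, unclass(grads))
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  new_params <- tree_map(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                         unclass(params), state$m, state$v)
  class(new_params) <- class(params)
  list(params = new_params, state = state)
}

case_mesh <- function(cs) {
  if (!is.null(cs$mesh)) cs$mesh else read_obj(cs$mesh_path, cs$case_id)
}

case_sheet <- function(cs) {
  if (!is.null(cs$sheet)) cs$sheet else read_label_json(cs$label_path, examiner = TRUE)
}

#' Fit the point-cloud scoring network
#'
#' Preprocesses every training mesh into a normalized deterministic point
#' cloud, then trains the network to minimize [mae_loss()] over the 9 rubric
#' outputs. Training runs in blocks of epochs (default two blocks of 50); the
#' optimizer state is reinitialized at the start of each block. After every
#' epoch the full-training-set MAE is recomputed and a checkpoint is written
#' (when `checkpoint_dir` is given); the parameters from the epoch with the
#' lowest training MAE are restored as the fitted model (ties go to the
#' earliest epoch). Cases tagged as test-split are refused outright.
#'
#' @param cases list of [labeled_case()] / `synthetic_case` objects (each
#'   carrying a mesh or mesh path, a reference sheet, and a split tag).
#' @param config a [model_config()]; its `n_points` sets the training cloud
#'   resolution.
#' @param epochs integer vector of epoch-block lengths.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param seed training seed (shuffling); initialization uses `config$seed`.
#' @param sampler_seed seed of the deterministic surface sampler.
#' @param checkpoint_dir optional directory for per-epoch checkpoints, the
#'   best-model copy and the loss-curve CSV.
#' @param weights optional per-output loss weights.
#' @param verbose print a line per epoch.
#' @return An object of class `prepnet`; see [predict.prepnet()],
#'   [summary.prepnet()], [plot.prepnet()], [residuals.prepnet()].
#' @export
fit_prepnet <- function(cases, config = model_config(),
                        epochs = c(50L, 50L), batch_size = 4L, lr = 1e-3,
                        seed = 123L, sampler_seed = 7L,
                        checkpoint_dir = NULL, weights = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(config, "model_config"), length(cases) >= 1L)
  splits <- vapply(cases, function(cs) cs$split %||% "train", "")
  if (any(splits == "test"))
    stop_named("prepscore_leakage",
               paste0("refusing to train on test-split case(s): ",
                      paste(vapply(cases[splits == "test"], `[[`, "", "case_id"),
                            collapse = ", ")))
  scfg <- sampler_config(n_points = config$n_points, seed = sampler_seed)
  mats <- lapply(cases, function(cs)
    preprocess_mesh(case_mesh(cs), scfg)$points)
  targets <- t(vapply(cases, function(cs) sheet_to_target(case_sheet(cs)),
                      numeric(config$n_outputs)))
  n <- length(cases)
  w <- weights %||% rep(1, config$n_outputs)

  params <- init_params(config)
  norms <- init_norms(config)
  if (!is.null(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  curve <- numeric(0)
  best_mae <- Inf
  best_epoch <- NA_integer_
  best_params <- params
  best_norms <- norms
  epoch_global <- 0L

  for (block in epochs) {
    state <- adam_init(params)
    for (e in seq_len(block)) {
      epoch_global <- epoch_global + 1L
      ord <- with_seed(derive_seed(seed, sprintf("shuffle_%d", epoch_global)),
                       sample.int(n))
      starts <- seq(1L, n, by = batch_size)
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + batch_size - 1L, n)]
        fwd <- forward_full(mats[idx], params, config, norms, training = TRUE)
        norms <- fwd$norms
        diff <- fwd$Y - targets[idx, , drop = FALSE]
        dY <- sweep(sign(diff), 2L, w, "*") / (length(idx) * sum(w))
        grads <- backward_full(params, config, fwd, dY)
        upd <- adam_step(params, grads, state, lr = lr)
        params <- upd$params
        state <- upd$state
      }
      Y_all <- forward_full(mats, params, config, norms, training = FALSE)$Y
      train_mae <- mae_loss(Y_all, targets, w)
      curve <- c(curve, train_mae)
      if (!is.null(checkpoint_dir)) {
        saveRDS(list(epoch = epoch_global, params = params, norms = norms,
                     train_mae = train_mae, timestamp = Sys.time(),
                     config = config, sampler_seed = as.integer(sampler_seed)),
                file.path(checkpoint_dir, sprintf("epoch_%04d.rds", epoch_global)))
      }
      if (train_mae < best_mae) {
        best_mae <- train_mae
        best_epoch <- epoch_global
        best_params <- params
        best_norms <- norms
      }
      if (verbose)
        message(sprintf("epoch %3d  training MAE %.4f", epoch_global, train_mae))
    }
  }

  curve_df <- data.frame(epoch = seq_along(curve), train_mae = curve)
  if (!is.null(checkpoint_dir)) {
    write.csv(curve_df, file.path(checkpoint_dir, "loss_curve.csv"),
              row.names = FALSE)
    if (!is.na(best_epoch))
      saveRDS(list(epoch = best_epoch, params = best_params, norms = best_norms,
                   train_mae = best_mae, timestamp = Sys.time(),
                   config = config, sampler_seed = as.integer(sampler_seed)),
              file.path(checkpoint_dir, "best.rds"))
  }
  fitted_Y <- forward_full(mats, best_params, config, best_norms,
                           training = FALSE)$Y
  structure(list(config = config, sampler_seed = as.integer(sampler_seed),
                 params = best_params, norms = best_norms,
                 final_params = params, final_norms = norms,
                 best_epoch = best_epoch, best_mae = best_mae,
                 curve = curve_df,
                 case_ids = vapply(cases, `[[`, "", "case_id"),
                 targets = targets, fitted = fitted_Y,
                 epochs = epochs, batch_size = batch_size, lr = lr,
                 seed = as.integer(seed), weights = w,
                 checkpoint_dir = checkpoint_dir),
            class = "prepnet")
}

#' Restore the best checkpoint from a directory
#'
#' Reads every `epoch_*.rds` checkpoint and returns the one with the lowest
#' recorded training MAE; ties break to the earliest epoch.
#'
#' @param checkpoint_dir directory written by [fit_prepnet()].
#' @return A list with `epoch`, `params`, `train_mae`, `config`.
#' @export
restore_best <- function(checkpoint_dir) {
  files <- list.files(checkpoint_dir, pattern = "^epoch_[0-9]{4}\\.rds$",
                      full.names = TRUE)
  if (length(files) == 0L)
    stop_named("prepscore_no_checkpoints",
               sprintf("no checkpoints in '%s'", checkpoint_dir))
  cps <- lapply(sort(files), readRDS)
  maes <- vapply(cps, `[[`, 0, "train_mae")
  cps[[which.min(maes)]]
}

# --- S3 methods on the fitted model -------------------------------------

#' @export
print.prepnet <- function(x, ...) {
  cat("Point-cloud rubric scoring network (prepnet)\n")
  cat(sprintf("  %d training cases, %d points/cloud, %s parameters\n",
              length(x$case_ids), x$config$n_points,
              format(n_parameters(x$params), big.mark = ",")))
  cat(sprintf("  epochs: %s (blocks)  best epoch: %s  best training MAE: %.3f\n",
              paste(x$epochs, collapse = "+"),
              ifelse(is.na(x$best_epoch), "-", x$best_epoch), x$best_mae))
  invisible(x)
}

#' Summarize a fitted scoring network
#'
#' @param object a `prepnet` fit.
#' @param ... unused.
#' @export
summary.prepnet <- function(object, ...) {
  res <- object$fitted[, "total"] - object$targets[, "total"]
  out <- list(n_cases = length(object$case_ids),
              n_parameters = n_parameters(object$params),
              best_epoch = object$best_epoch, best_mae = object$best_mae,
              curve = object$curve,
              total_residual_summary = summary(res))
  class(out) <- "summary.prepnet"
  out
}

#' @export
print.summary.prepnet <- function(x, ...) {
  cat(sprintf("prepnet fit: %d cases, %s parameters\n", x$n_cases,
              format(x$n_parameters, big.mark = ",")))
  cat(sprintf("best epoch %s, training MAE %.4f (curve over %d epochs)\n",
              ifelse(is.na(x$best_epoch), "-", x$best_epoch), x$best_mae,
              nrow(x$curve)))
  cat("training total-score residuals (predicted - reference):\n")
  print(x$total_residual_summary)
  invisible(x)
}

#' Predict rubric scores for new meshes
#'
#' Applies the training-time preprocessing (deterministic sampling at the
#' fitted resolution with the fitted sampler seed, unit-sphere
#' normalization), so the same OBJ always yields the same scores.
#'
#' @param object a `prepnet` fit.
#' @param newdata a `tri_mesh`, an OBJ path, a normalized `point_cloud`, a
#'   labeled/synthetic case, or a list of any of these.
#' @param type `"sheet"` for [predict_sheet()] objects, `"matrix"` for the
#'   raw output matrix.
#' @param ... unused.
#' @return A `predicted_sheet` (single input, `type = "sheet"`), a list of
#'   them, or the numeric output matrix.
#' @export
predict.prepnet <- function(object, newdata, type = c("sheet", "matrix"), ...) {
  type <- match.arg(type)
  single <- !is.list(newdata) || inherits(newdata, c("tri_mesh", "point_cloud",
                                                     "labeled_case", "synthetic_case"))
  items <- if (single) list(newdata) else newdata
  scfg <- sampler_config(n_points = object$config$n_points,
                         seed = object$sampler_seed)
  clouds <- lapply(items, function(it) {
    if (inherits(it, "point_cloud")) return(it)
    if (inherits(it, c("labeled_case", "synthetic_case"))) it <- case_mesh(it)
    preprocess_mesh(it, scfg)
  })
  if (type == "matrix")
    return(forward(clouds, object$params, object$config, object$norms))
  preds <- lapply(clouds, predict_sheet, params = object$params,
                  config = object$config, norms = object$norms)
  if (single) preds[[1L]] else preds
}

#' @export
fitted.prepnet <- function(object, ...) object$fitted

#' Training-set residuals of the total score
#'
#' @param object a `prepnet` fit.
#' @param ... unused.
#' @return Named vector of predicted-minus-reference totals (rubric points)
#'   on the training cases, at the restored best epoch.
#' @export
residuals.prepnet <- function(object, ...) {
  setNames(object$fitted[, "total"] - object$targets[, "total"],
           object$case_ids)
}

#' Plot the training loss curve
#'
#' @param x a `prepnet` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.prepnet <- function(x, ...) {
  graphics::plot(x$curve$epoch, x$curve$train_mae, type = "l",
                 xlab = "epoch", ylab = "training MAE (rubric points)", ...)
  if (!is.na(x$best_epoch))
    graphics::points(x$best_epoch, x$best_mae, pch = 19, col = "red")
  invisible(x)
}
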