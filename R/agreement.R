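# Method-agreement statistics for predicted vs. reference rubric totals:
# MAE, RMSE, Pearson r, tie-corrected Spearman rho, Lin's concordance
# correlation with its accuracy component, Bland-Altman bias and 95% limits
# of agreement, ICC(2,1) for rater reliability, and within-threshold
# accuracy. Differences are oriented predicted - reference throughout.

#' Paired predicted/reference total scores
#'
#' @param reference,predicted numeric vectors of rubric totals.
#' @param case_ids optional identifiers.
#' @return An object of class `paired_scores`.
#' @export
paired_scores <- function(reference, predicted, case_ids = NULL) {
  reference <- as.numeric(reference)
  predicted <- as.numeric(predicted)
  if (length(reference) != length(predicted))
    stop_named("prepscore_shape", "reference and predicted lengths differ")
  if (length(reference) < 2L)
    stop_named("prepscore_shape", "need at least 2 paired scores")
  if (anyNA(reference) || anyNA(predicted) ||
      any(!is.finite(c(reference, predicted))))
    stop_named("prepscore_bad_input", "paired scores must be finite")
  structure(list(reference = reference, predicted = predicted,
                 case_ids = case_ids %||% as.character(seq_along(reference))),
            class = "paired_scores")
}

check_variance <- function(p) {
  if (stats::var(p$reference) == 0 || stats::var(p$predicted) == 0)
    stop_named("prepscore_degenerate",
               "zero variance in scores; correlation undefined")
}

#' Agreement error metrics
#'
#' @param p a [paired_scores()].
#' @return Rubric points.
#' @export
mae <- function(p) mean(abs(p$predicted - p$reference))

#' @rdname mae
#' @export
rmse <- function(p) sqrt(mean((p$predicted - p$reference)^2))

#' Correlation between predicted and reference scores
#'
#' `spearman_rho` is Pearson on mid-ranks (tie-corrected), which matters
#' because rubric totals contain ties.
#'
#' @param p a [paired_scores()].
#' @return Correlation in [-1, 1].
#' @export
pearson_r <- function(p) {
  check_variance(p)
  stats::cor(p$predicted, p$reference)
}

#' @rdname pearson_r
#' @export
spearman_rho <- function(p) {
  check_variance(p)
  stats::cor(p$predicted, p$reference, method = "spearman")
}

#' Lin's concordance correlation coefficient
#'
#' rho_c = 2 s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2), with population
#' (1/n) moments by default (Lin's original convention); the accuracy
#' component is C_b = rho_c / r, so rho_c = r * C_b.
#'
#' @param p a [paired_scores()].
#' @param population logical; `FALSE` uses n-1 moments instead.
#' @return A list with `rho_c` and `c_b`.
#' @export
lin_ccc <- function(p, population = TRUE) {
  check_variance(p)
  x <- p$predicted
  y <- p$reference
  n <- length(x)
  denom <- if (population) n else n - 1L
  sxy <- sum((x - mean(x)) * (y - mean(y))) / denom
  sx2 <- sum((x - mean(x))^2) / denom
  sy2 <- sum((y - mean(y))^2) / denom
  rho_c <- 2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
  list(rho_c = rho_c, c_b = rho_c / pearson_r(p))
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences are predicted - reference; limits are bias +/- 1.96 times the
#' sample (n-1) standard deviation of the differences.
#'
#' @param p a [paired_scores()].
#' @return A list with `bias`, `loa_low`, `loa_high` (rubric points).
#' @export
bland_altman <- function(p) {
  d <- p$predicted - p$reference
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' ICC(2,1): two-way random effects, absolute agreement, single rater
#'
#' Computed from the two-way mean squares: rows are cases, columns raters;
#' ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n).
#'
#' @param m numeric matrix, n cases x k raters, complete.
#' @return The intraclass correlation coefficient.
#' @export
icc_2_1 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L || anyNA(m))
    stop_named("prepscore_bad_input", "need a complete matrix with >= 2 cases and >= 2 raters")
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1L)
  msc <- n * sum((col_m - grand)^2) / (k - 1L)
  resid <- m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  mse <- sum(resid^2) / ((n - 1L) * (k - 1L))
  if (msr == 0 && mse == 0)
    stop_named("prepscore_degenerate", "all ratings equal; ICC undefined")
  (msr - mse) / (msr + (k - 1L) * mse + k * (msc - mse) / n)
}

#' Percentage of predictions within score thresholds
#'
#' For each threshold t, the percentage of cases with |predicted -
#' reference| <= t (with a 1e-9 absolute guard against float noise).
#'
#' @param p a [paired_scores()].
#' @param thresholds numeric vector of thresholds in rubric points.
#' @return Named numeric vector of percentages.
#' @export
pct_within <- function(p, thresholds = c(1, 2)) {
  d <- abs(p$predicted - p$reference)
  setNames(vapply(thresholds,
                  function(t) 100 * mean(d <= t + 1e-9), 0),
           paste0("within_", thresholds))
}

#' Full agreement report
#'
#' @param p a [paired_scores()].
#' @param thresholds thresholds for [pct_within()].
#' @return An object of class `agreement_report` with fields `n`, `mae`,
#'   `rmse`, `pearson_r`, `spearman_rho`, `ccc`, `cb`, `bias`, `loa_low`,
#'   `loa_high`, `pct_within`.
#' @export
agreement_report <- function(p, thresholds = c(1, 2)) {
  stopifnot(inherits(p, "paired_scores"))
  ccc <- lin_ccc(p)
  ba <- bland_altman(p)
  structure(list(n = length(p$reference),
                 mae = mae(p), rmse = rmse(p),
                 pearson_r = pearson_r(p), spearman_rho = spearman_rho(p),
                 ccc = ccc$rho_c, cb = ccc$c_b,
                 bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
                 pct_within = pct_within(p, thresholds)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement over %d cases (predicted vs reference totals)\n", x$n))
  cat(sprintf("  MAE %.3f  RMSE %.3f  r %.3f  rho %.3f\n",
              x$mae, x$rmse, x$pearson_r, x$spearman_rho))
  cat(sprintf("  Lin rho_c %.3f (Cb %.3f)  bias %+.3f  LoA [%.3f, %.3f]\n",
              x$ccc, x$cb, x$bias, x$loa_low, x$loa_high))
  for (nm in names(x$pct_within))
    cat(sprintf("  %s points: %.1f%%\n",
                sub("within_", "within +/-", nm), x$pct_within[[nm]]))
  invisible(x)
}

#' @export
as.list.agreement_report <- function(x, ...) unclass(x)

#' Evaluate a fitted model on labeled cases
#'
#' Runs the shared preprocessing and prediction on every case, pairs the
#' direct total output against the reference totals, and computes the full
#' agreement suite plus a per-criterion predicted-vs-true table.
#'
#' @param fit a `prepnet` model.
#' @param cases list of labeled/synthetic cases with reference sheets.
#' @param thresholds thresholds for [pct_within()].
#' @return A list with `report` (an `agreement_report`), `pairs`
#'   (a `paired_scores`), and `table` (data.frame: one row per criterion and
#'   the total, true and predicted values per case).
#' @export
evaluate_model <- function(fit, cases, thresholds = c(1, 2)) {
  stopifnot(inherits(fit, "prepnet"), length(cases) >= 2L)
  Y <- predict(fit, cases, type = "matrix")
  refs <- t(vapply(cases, function(cs) sheet_to_target(case_sheet(cs)),
                   numeric(fit$config$n_outputs)))
  ids <- vapply(cases, `[[`, "", "case_id")
  p <- paired_scores(refs[, "total"], Y[, "total"], case_ids = ids)
  keys <- output_keys()
  tab <- do.call(rbind, lapply(keys, function(k) {
    rbind(data.frame(criterion = k, kind = "true", case_id = ids,
                     value = refs[, k], stringsAsFactors = FALSE),
          data.frame(criterion = k, kind = "predicted", case_id = ids,
                     value = Y[, k], stringsAsFactors = FALSE))
  }))
  list(report = agreement_report(p, thresholds), pairs = p, table = tab)
}
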