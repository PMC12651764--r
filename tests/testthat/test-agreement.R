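# Agreement statistics against independent brute-force oracles and their
# closed-form/degenerate behaviour.

# --- naive oracles, written from the definitions -------------------------
slow_mae <- function(x, y) sum(abs(y - x)) / length(x)
slow_rmse <- function(x, y) sqrt(sum((y - x)^2) / length(x))
slow_pearson <- function(x, y) {
  xm <- sum(x) / length(x); ym <- sum(y) / length(y)
  sum((x - xm) * (y - ym)) / sqrt(sum((x - xm)^2) * sum((y - ym)^2))
}
slow_spearman <- function(x, y) slow_pearson(rank(x), rank(y))
slow_ccc <- function(x, y) {
  n <- length(x)
  xm <- mean(x); ym <- mean(y)
  sxy <- sum((x - xm) * (y - ym)) / n
  2 * sxy / (sum((x - xm)^2) / n + sum((y - ym)^2) / n + (xm - ym)^2)
}
slow_ba <- function(x, y) {
  d <- y - x
  c(mean(d), mean(d) - 1.96 * sd(d), mean(d) + 1.96 * sd(d))
}
# two-way ANOVA route for ICC(2,1)
slow_icc <- function(m) {
  df <- data.frame(score = as.vector(m),
                   case = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  ms <- summary(stats::aov(score ~ case + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- nrow(m); k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

random_pairs <- function(n) {
  ref <- round_to_half(runif(n, 0, 20))
  paired_scores(ref, pmin(20, pmax(0, ref + rnorm(n))))
}

test_that("every statistic matches its brute-force oracle on random instances", {
  set.seed(2024)
  for (k in 1:25) {
    n <- sample(3:20, 1)
    p <- random_pairs(n)
    x <- p$reference; y <- p$predicted
    expect_lt(abs(mae(p) - slow_mae(x, y)), 1e-9)
    expect_lt(abs(rmse(p) - slow_rmse(x, y)), 1e-9)
    expect_lt(abs(pearson_r(p) - slow_pearson(x, y)), 1e-9)
    expect_lt(abs(spearman_rho(p) - slow_spearman(x, y)), 1e-9)
    cc <- lin_ccc(p)
    expect_lt(abs(cc$rho_c - slow_ccc(x, y)), 1e-9)
    expect_lt(abs(cc$c_b - slow_ccc(x, y) / slow_pearson(x, y)), 1e-9)
    ba <- bland_altman(p)
    expect_lt(max(abs(unlist(ba) - slow_ba(x, y))), 1e-9)

    m <- matrix(runif(n * 3, 0, 20), n, 3)
    expect_lt(abs(icc_2_1(m) - slow_icc(m)), 1e-9)
  }
})

test_that("closed forms and invariants hold", {
  x <- c(2, 5, 9, 14, 17)
  p_id <- paired_scores(x, x)
  expect_equal(mae(p_id), 0)
  expect_equal(rmse(p_id), 0)
  expect_equal(pearson_r(p_id), 1)
  expect_equal(lin_ccc(p_id)$rho_c, 1)
  expect_equal(lin_ccc(p_id)$c_b, 1)
  expect_equal(unlist(bland_altman(p_id)), c(bias = 0, loa_low = 0, loa_high = 0))
  expect_equal(unname(pct_within(p_id, c(0, 1))), c(100, 100))

  # perfect line and reversed ranks
  p_line <- paired_scores(x, 2 * x + 1)
  expect_equal(pearson_r(p_line), 1)
  expect_equal(spearman_rho(p_line), 1)
  expect_equal(spearman_rho(paired_scores(x, rev(x))), -1)

  # constant shift: r stays 1, concordance drops, Cb = rho_c
  p_shift <- paired_scores(x, x + 3)
  expect_equal(pearson_r(p_shift), 1)
  expect_lt(lin_ccc(p_shift)$rho_c, 1)
  expect_equal(lin_ccc(p_shift)$c_b, lin_ccc(p_shift)$rho_c)

  # d = {-1, +1}: closed-form limits
  ba <- bland_altman(paired_scores(c(5, 10), c(4, 11)))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(2))
  expect_equal(ba$loa_low, -1.96 * sqrt(2))

  # identical raters with varying cases agree perfectly; a shifted rater
  # is penalized by the absolute-agreement form
  m <- cbind(x, x)
  expect_equal(icc_2_1(m), 1)
  expect_lt(icc_2_1(cbind(x, x + 2)), 1)

  set.seed(5)
  p <- random_pairs(12)
  expect_gte(rmse(p), mae(p))
  ba2 <- bland_altman(p)
  expect_lte(ba2$loa_low, ba2$bias)
  expect_lte(ba2$bias, ba2$loa_high)
  pw <- pct_within(p, c(0, 0.5, 1, 2, 5))
  expect_true(all(diff(pw) >= 0))
  expect_lte(abs(lin_ccc(p)$rho_c), abs(pearson_r(p)))

  # adding a constant shifts the bias by it, keeps r, never raises rho_c
  shifted <- paired_scores(p$reference, p$predicted + 1.5)
  expect_equal(bland_altman(shifted)$bias, ba2$bias + 1.5)
  expect_equal(pearson_r(shifted), pearson_r(p))
  expect_lte(lin_ccc(shifted)$rho_c, lin_ccc(p)$rho_c + 1e-12)
})

test_that("degenerate inputs raise named errors", {
  flat <- paired_scores(rep(3, 5), 1:5)
  expect_error(pearson_r(flat), class = "prepscore_degenerate")
  expect_error(spearman_rho(flat), class = "prepscore_degenerate")
  expect_error(lin_ccc(flat), class = "prepscore_degenerate")
  expect_error(icc_2_1(matrix(2, 4, 2)), class = "prepscore_degenerate")
  expect_error(paired_scores(1, 1), class = "prepscore_shape")
  expect_error(paired_scores(c(1, NA), c(1, 2)), class = "prepscore_bad_input")
  expect_error(icc_2_1(matrix(c(1, NA, 2, 3), 2, 2)),
               class = "prepscore_bad_input")
})

test_that("pilot fixture tables load with the printed values intact", {
  tr <- pilot_score_table("train")
  te <- pilot_score_table("test")
  expect_equal(length(unique(tr$sample)), 20L)
  expect_equal(length(unique(te$sample)), 10L)
  expect_setequal(unique(tr$criterion), c(rubric_criteria()$key, "total"))
  # the printed table keeps its internal inconsistencies verbatim: one
  # occlusal-preservation cell above the rubric maximum
  occ <- te[te$criterion == "occlusal_preservation" & te$sample == 10, ]
  expect_equal(occ$true, 2)
  p <- pilot_total_pairs("test")
  expect_equal(p$reference[1], 11.5)
  expect_length(p$reference, 10L)
})

test_that("evaluating a trained model produces a complete coherent report", {
  cases <- small_cohort(n = 8, seed = 5)
  train <- Filter(function(cs) cs$split == "train", cases)
  test <- Filter(function(cs) cs$split == "test", cases)
  fit <- fit_prepnet(train, tiny_config(), epochs = c(3L), batch_size = 3)
  ev <- evaluate_model(fit, c(test, train[1:3]))
  expect_s3_class(ev$report, "agreement_report")
  expect_gte(ev$report$rmse, ev$report$mae)
  expect_true(all(diff(ev$report$pct_within) >= 0))
  expect_equal(ev$report$n, length(test) + 3L)
  expect_setequal(unique(ev$table$criterion), c(rubric_criteria()$key, "total"))
  expect_setequal(unique(ev$table$kind), c("true", "predicted"))
  # report serializes to JSON
  js <- jsonlite::toJSON(as.list(ev$report), auto_unbox = TRUE)
  expect_true(jsonlite::validate(js))
})
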