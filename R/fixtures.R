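#' Per-case scores from the scoring pilot
#'
#' The per-case rubric scores (examiner-averaged "true" values and model
#' predictions) reported by the clinician-led scoring pilot this package
#' reimplements: 20 training cases and 10 held-out test cases, rounded to
#' one decimal place as printed. Shipped as evaluation fixtures so the
#' agreement statistics can be exercised against published values.
#'
#' Two caveats are inherited from the printed tables and preserved verbatim:
#' the published headline statistics were computed on unrounded scores, so
#' statistics recomputed from these rounded values differ slightly (e.g. the
#' test-set Bland-Altman bias); and two test-set cells are internally
#' inconsistent (sample 10 prints an occlusal-preservation score of 2,
#' above the 1-point maximum, and sample 7's printed criteria sum to 14
#' against a printed total of 12). [score_sheet()] validation would reject
#' those cells; the fixture therefore stays a plain table, and total-score
#' agreement uses the printed totals row.
#'
#' @param split `"train"` (20 cases) or `"test"` (10 cases).
#' @return A data.frame with columns `sample`, `criterion` (rubric keys plus
#'   `"total"`), `true`, `predicted`.
#' @export
pilot_score_table <- function(split = c("train", "test")) {
  split <- match.arg(split)
  path <- system.file("extdata", sprintf("pilot_%s_scores.csv", split),
                      package = "prepscore", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname pilot_score_table
#' @return `pilot_total_pairs` returns the printed total scores as a
#'   [paired_scores()] object.
#' @export
pilot_total_pairs <- function(split = c("train", "test")) {
  tab <- pilot_score_table(split)
  tot <- tab[tab$criterion == "total", ]
  tot <- tot[order(tot$sample), ]
  paired_scores(tot$true, tot$predicted, case_ids = as.character(tot$sample))
}
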