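# Rubric arithmetic, examiner averaging, JSON labels, split validation.

test_that("rubric structure carries the 20-point budget and the damage deduction", {
  r <- rubric_criteria()
  expect_equal(sum(r$max[r$max > 0]), 20)
  expect_equal(r$min[r$key == "adjacent_damage"], -4)
  expect_true(all(r$min[r$key != "adjacent_damage"] == 0))
})

test_that("total_score reproduces printed pilot totals and rubric edge rules", {
  # held-out pilot case: modest marks and a 2-point deduction
  s4 <- score_sheet("t2_s4", c(clearance_buccal = 0, clearance_lingual = 1,
                               clearance_gingival = 0, preservation_between = 2,
                               occlusal_preservation = 1, caries_removal = 7,
                               no_undermined_enamel = 0, adjacent_damage = -2),
                    examiner = TRUE)
  expect_equal(total_score(s4), 9)
  # training pilot case with full marks
  s8 <- score_sheet("t1_s8", c(clearance_buccal = 2, clearance_lingual = 2,
                               clearance_gingival = 2, preservation_between = 2,
                               occlusal_preservation = 1, caries_removal = 9,
                               no_undermined_enamel = 2, adjacent_damage = 0),
                    examiner = TRUE)
  expect_equal(total_score(s8), 20)
  expect_equal(total_score(max_sheet()), 20)
  # pulp exposure zeroes everything
  perfect_but_pulp <- score_sheet("pulp", max_sheet()$values, pulp_exposure = TRUE)
  expect_equal(total_score(perfect_but_pulp), 0)
  # the deduction cannot push a total below zero
  zeroes <- score_sheet("low", c(clearance_buccal = 0, clearance_lingual = 0,
                                 clearance_gingival = 0, preservation_between = 0,
                                 occlusal_preservation = 0, caries_removal = 2,
                                 no_undermined_enamel = 0, adjacent_damage = -4))
  expect_equal(total_score(zeroes), 0)
  expect_error(score_sheet("bad", c(max_sheet()$values[-6], caries_removal = 9.5)),
               class = "prepscore_out_of_range")
  expect_error(score_sheet("frac", `[<-`(max_sheet()$values, "caries_removal", 8.3),
                           examiner = TRUE),
               class = "prepscore_granularity")
})

test_that("total_score is monotone in every criterion and bounded in [0, 20]", {
  r <- rubric_criteria()
  set.seed(404)
  for (i in 1:40) {
    s <- random_sheet()
    expect_gte(total_score(s), 0)
    expect_lte(total_score(s), 20)
    k <- sample(r$key, 1)
    bumped <- s$values
    bumped[k] <- min(bumped[k] + 0.5, r$max[r$key == k])
    s2 <- score_sheet(s$case_id, bumped, examiner = TRUE)
    expect_gte(total_score(s2), total_score(s))
  }
})

test_that("examiner averaging takes per-criterion means and ORs pulp exposure", {
  a <- max_sheet("c1", occlusal_preservation = 0, caries_removal = 8)
  b <- max_sheet("c1", occlusal_preservation = 1, caries_removal = 9)
  avg <- average_examiners(a, b)
  expect_equal(unname(avg$values["occlusal_preservation"]), 0.5)
  expect_equal(unname(avg$values["caries_removal"]), 8.5)
  expect_identical(average_examiners(a, a)$values, a$values)
  # averaging commutes with totalling when no clamping/zeroing applies
  expect_equal(total_score(avg), (total_score(a) + total_score(b)) / 2)

  pulp <- score_sheet("c1", a$values, pulp_exposure = TRUE)
  expect_true(average_examiners(a, pulp)$pulp_exposure)
  expect_error(average_examiners(a, max_sheet("other")),
               class = "prepscore_case_mismatch")
})

test_that("JSON labels round-trip and are validated on read", {
  s <- max_sheet("json_case", caries_removal = 7.5, adjacent_damage = -1)
  path <- tempfile(fileext = ".json")
  write_label_json(s, path)
  back <- read_label_json(path, examiner = TRUE)
  expect_equal(back$values, s$values)
  expect_identical(back$case_id, "json_case")

  obj <- jsonlite::read_json(path)
  obj$caries_removal <- NULL
  p2 <- tempfile(fileext = ".json")
  jsonlite::write_json(obj, p2, auto_unbox = TRUE)
  expect_error(read_label_json(p2), class = "prepscore_schema")

  obj <- jsonlite::read_json(path)
  obj$total <- obj$total + 1
  p3 <- tempfile(fileext = ".json")
  jsonlite::write_json(obj, p3, auto_unbox = TRUE)
  expect_error(read_label_json(p3), class = "prepscore_total_inconsistent")

  p4 <- tempfile(fileext = ".json")
  writeLines("{not json", p4)
  expect_error(read_label_json(p4), class = "prepscore_bad_json")
  expect_error(read_label_json(tempfile()), class = "prepscore_missing_file")
})

test_that("validate_split flags duplicates and rigidly moved copies across splits", {
  dirs <- tempfile("cohort")
  cases <- small_cohort(n = 4, seed = 2, out_dir = dirs)
  lc <- lapply(cases, function(cs)
    labeled_case(cs$case_id, cs$mesh_path, cs$label_path, cs$sheet, cs$split))
  meshes <- setNames(lapply(cases, `[[`, "mesh"),
                     vapply(cases, `[[`, "", "case_id"))

  expect_equal(nrow(validate_split(lc, meshes)), 0L)

  # the same mesh content in both splits
  tr <- which(vapply(cases, `[[`, "", "split") == "train")[1]
  te <- which(vapply(cases, `[[`, "", "split") == "test")[1]
  meshes_dup <- meshes
  meshes_dup[[te]] <- meshes[[tr]]
  rep_dup <- validate_split(lc, meshes_dup)
  expect_true("duplicate_mesh" %in% rep_dup$kind)

  # a translated copy normalizes to the identical cloud: near-duplicate
  moved <- meshes[[tr]]
  moved$vertices <- moved$vertices + 2.5
  meshes_near <- meshes
  meshes_near[[te]] <- moved
  rep_near <- validate_split(lc, meshes_near)
  expect_true("near_duplicate" %in% rep_near$kind)

  # duplicated ids
  lc_dup <- c(lc, lc[1])
  expect_true("duplicate_id" %in%
                validate_split(lc_dup, c(meshes, meshes[1]))$kind)
})
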