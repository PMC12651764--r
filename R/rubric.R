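#' The 20-point cavity-preparation rubric
#'
#' Nine items: seven positively scored criteria whose maxima sum to 20, one
#' deduction for iatrogenic damage to the adjacent tooth (0 down to -4
#' points: up to -2 for minor damage under 1 mm, down to -4 for moderate
#' damage of 1-2 mm), and a pulp-exposure flag that zeroes the total.
#'
#' @return A data.frame with columns `key`, `label`, `min`, `max`, one row
#'   per scored criterion (the pulp flag is not a row; it is a boolean on the
#'   score sheet).
#' @export
rubric_criteria <- function() {
  data.frame(
    key = c("clearance_buccal", "clearance_lingual", "clearance_gingival",
            "preservation_between", "occlusal_preservation", "caries_removal",
            "no_undermined_enamel", "adjacent_damage"),
    label = c("Proximal clearance buccal", "Proximal clearance lingual",
              "Proximal clearance gingival",
              "Preservation between occlusal and proximal",
              "Occlusal preservation", "Caries removal",
              "No undermined enamel", "Damage to adjacent teeth"),
    min = c(0, 0, 0, 0, 0, 0, 0, -4),
    max = c(2, 2, 2, 2, 1, 9, 2, 0),
    stringsAsFactors = FALSE
  )
}

# The 20-point ceiling is the sum of positive maxima; kept as a function so
# sheet validation and the network's total-output bound share one source.
rubric_max_total <- function() {
  r <- rubric_criteria()
  sum(r$max[r$max > 0])
}

#' Construct a score sheet
#'
#' One value per rubric criterion plus the pulp-exposure flag. Examiner
#' (reference) sheets are additionally required to sit on the half-point grid,
#' since reference scores are averages of two integer-valued examiner marks.
#'
#' @param case_id case identifier.
#' @param values named numeric vector/list with one entry per criterion key
#'   of [rubric_criteria()]; `adjacent_damage` is stored as its (non-positive)
#'   signed value.
#' @param pulp_exposure logical; `TRUE` zeroes the total.
#' @param examiner logical; enforce half-point granularity.
#' @return An object of class `score_sheet`.
#' @export
score_sheet <- function(case_id, values, pulp_exposure = FALSE,
                        examiner = FALSE) {
  rub <- rubric_criteria()
  values <- unlist(values)
  missing <- setdiff(rub$key, names(values))
  if (length(missing) > 0L)
    stop_named("prepscore_schema",
               paste0("missing criterion value(s): ", paste(missing, collapse = ", ")))
  vals <- as.numeric(values[rub$key])
  if (anyNA(vals) || any(!is.finite(vals)))
    stop_named("prepscore_schema", "non-numeric criterion value")
  bad <- vals < rub$min - 1e-9 | vals > rub$max + 1e-9
  if (any(bad))
    stop_named("prepscore_out_of_range",
               paste0("criterion value out of range: ",
                      paste(sprintf("%s=%g", rub$key[bad], vals[bad]), collapse = ", ")))
  if (examiner && any(abs(vals * 2 - round(vals * 2)) > 1e-9))
    stop_named("prepscore_granularity",
               "examiner sheet values must be multiples of 0.5")
  names(vals) <- rub$key
  structure(list(case_id = as.character(case_id), values = vals,
                 pulp_exposure = isTRUE(pulp_exposure), examiner = examiner),
            class = "score_sheet")
}

#' @export
print.score_sheet <- function(x, ...) {
  cat(sprintf("<score_sheet '%s'%s>\n", x$case_id,
              if (x$pulp_exposure) ", PULP EXPOSURE (total 0)" else ""))
  print(round(x$values, 3))
  cat(sprintf("total: %g\n", total_score(x)))
  invisible(x)
}

#' Total rubric score of a sheet
#'
#' Sum of all criterion values (the adjacent-damage deduction enters with its
#' negative sign), zeroed entirely on pulp exposure and clamped below at 0.
#' The result never exceeds 20 points.
#'
#' @param sheet a [score_sheet()].
#' @return Total score in rubric points.
#' @export
total_score <- function(sheet) {
  stopifnot(inherits(sheet, "score_sheet"))
  if (sheet$pulp_exposure) return(0)
  max(0, min(sum(sheet$values), rubric_max_total()))
}

#' Average two examiners' sheets into the reference sheet
#'
#' Per-criterion arithmetic mean; pulp exposure is flagged if either examiner
#' flagged it. The result is the reference (ground-truth) score for a case.
#'
#' @param a,b [score_sheet()]s for the same `case_id`.
#' @return A `score_sheet` (examiner-grade, half-point values).
#' @export
average_examiners <- function(a, b) {
  stopifnot(inherits(a, "score_sheet"), inherits(b, "score_sheet"))
  if (!identical(a$case_id, b$case_id))
    stop_named("prepscore_case_mismatch",
               sprintf("case ids differ: '%s' vs '%s'", a$case_id, b$case_id))
  score_sheet(a$case_id, (a$values + b$values) / 2,
              pulp_exposure = a$pulp_exposure || b$pulp_exposure,
              examiner = TRUE)
}

#' Write / read a JSON score label
#'
#' The label schema of record: `case_id`, one numeric field per criterion key
#' of [rubric_criteria()], `pulp_exposure`, and `total`. On read, bounds are
#' validated and the stored total is checked against [total_score()].
#'
#' @param sheet a [score_sheet()].
#' @param path JSON file path.
#' @return `write_label_json` returns `path` invisibly; `read_label_json`
#'   returns a `score_sheet`.
#' @export
write_label_json <- function(sheet, path) {
  stopifnot(inherits(sheet, "score_sheet"))
  obj <- c(list(case_id = sheet$case_id), as.list(sheet$values),
           list(pulp_exposure = sheet$pulp_exposure,
                total = total_score(sheet)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_json
#' @param examiner logical passed through to [score_sheet()] validation.
#' @export
read_label_json <- function(path, examiner = FALSE) {
  if (!file.exists(path))
    stop_named("prepscore_missing_file", sprintf("label file not found: '%s'", path))
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop_named("prepscore_bad_json",
                               sprintf("malformed JSON in '%s': %s", path,
                                       conditionMessage(e))))
  rub <- rubric_criteria()
  missing <- setdiff(c("case_id", rub$key, "pulp_exposure", "total"), names(obj))
  if (length(missing) > 0L)
    stop_named("prepscore_schema",
               paste0("label '", path, "' missing field(s): ",
                      paste(missing, collapse = ", ")))
  sheet <- score_sheet(obj$case_id, obj[rub$key],
                       pulp_exposure = isTRUE(obj$pulp_exposure),
                       examiner = examiner)
  if (abs(as.numeric(obj$total) - total_score(sheet)) > 1e-6)
    stop_named("prepscore_total_inconsistent",
               sprintf("stored total %g disagrees with recomputed total %g in '%s'",
                       as.numeric(obj$total), total_score(sheet), path))
  sheet
}

#' A labeled case: mesh file + score label + split tag
#'
#' @param case_id case identifier.
#' @param mesh_path path to the OBJ mesh.
#' @param label_path path to the JSON label.
#' @param sheet the reference [score_sheet()].
#' @param split `"train"` or `"test"`.
#' @return An object of class `labeled_case`.
#' @export
labeled_case <- function(case_id, mesh_path, label_path, sheet,
                         split = c("train", "test")) {
  split <- match.arg(split)
  stopifnot(inherits(sheet, "score_sheet"))
  structure(list(case_id = as.character(case_id), mesh_path = mesh_path,
                 label_path = label_path, sheet = sheet, split = split),
            class = "labeled_case")
}

# Canonical content hash of a mesh, invariant to file formatting.
mesh_hash <- function(mesh) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(c(sprintf("%.9g", round(mesh$vertices, 9)),
               sprintf("%d", mesh$faces)), tmp)
  unname(tools::md5sum(tmp))
}

# Mean nearest-neighbour distance between two normalized low-resolution
# clouds; rigid copies of a mesh normalize to the same cloud (distance 0).
cloud_nn_distance <- function(mesh_a, mesh_b, n_probe = 256L, seed = 1L) {
  cfg <- function(id) sampler_config(n_points = n_probe, seed = seed)
  pa <- normalize_point_cloud(sample_point_cloud(
    tri_mesh(mesh_a$vertices, mesh_a$faces, "probe"), cfg()))$points
  pb <- normalize_point_cloud(sample_point_cloud(
    tri_mesh(mesh_b$vertices, mesh_b$faces, "probe"), cfg()))$points
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  mean(sqrt(pmax(apply(d2, 1L, min), 0)))
}

#' Check a train/test split for duplicates and leakage
#'
#' Flags duplicate case ids, byte-identical mesh content across splits, and
#' near-duplicates: meshes whose normalized probe clouds have mean
#' nearest-neighbour distance below `threshold` (a rigidly moved or uniformly
#' rescaled copy normalizes to the identical cloud, distance 0).
#'
#' @param cases list of [labeled_case()]s.
#' @param meshes optional named list of `tri_mesh` keyed by case_id; read from
#'   `mesh_path` when absent.
#' @param threshold near-duplicate distance threshold (normalized units).
#' @return A data.frame report with columns `kind`, `case_a`, `case_b`
#'   (empty when the split is clean).
#' @export
validate_split <- function(cases, meshes = NULL, threshold = 1e-3) {
  ids <- vapply(cases, `[[`, "", "case_id")
  splits <- vapply(cases, `[[`, "", "split")
  report <- data.frame(kind = character(), case_a = character(),
                       case_b = character(), stringsAsFactors = FALSE)
  dup <- ids[duplicated(ids)]
  for (d in unique(dup))
    report <- rbind(report, data.frame(kind = "duplicate_id", case_a = d, case_b = d))
  if (is.null(meshes))
    meshes <- setNames(lapply(cases, function(cs) read_obj(cs$mesh_path, cs$case_id)), ids)
  hashes <- vapply(meshes[ids], mesh_hash, "")
  tr <- which(splits == "train")
  te <- which(splits == "test")
  for (i in tr) for (j in te) {
    if (hashes[i] == hashes[j]) {
      report <- rbind(report, data.frame(kind = "duplicate_mesh",
                                         case_a = ids[i], case_b = ids[j]))
    } else if (cloud_nn_distance(meshes[[ids[i]]], meshes[[ids[j]]]) < threshold) {
      report <- rbind(report, data.frame(kind = "near_duplicate",
                                         case_a = ids[i], case_b = ids[j]))
    }
  }
  report
}
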