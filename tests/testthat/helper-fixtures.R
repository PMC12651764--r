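# Shared fixtures, all built in code at test time.

write_obj_text <- function(lines) {
  path <- tempfile(fileext = ".obj")
  writeLines(lines, path)
  path
}

# One right triangle in the z = 0 plane.
single_triangle_mesh <- function() {
  tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
           rbind(c(1L, 2L, 3L)), source_id = "tri")
}

# Two parallel triangles with area ratio 9:1; membership readable off z.
two_plane_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 3, 0),   # area 9 at z = 0
             c(0, 0, 1), c(2, 0, 1), c(0, 1, 1))   # area 1 at z = 1
  tri_mesh(v, rbind(c(1L, 2L, 3L), c(4L, 5L, 6L)), source_id = "planes")
}

# Irregular tetrahedron (4 faces, distinct areas) for area-uniform sampling.
tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 2, 0), c(0, 0, 1))
  f <- rbind(c(1L, 3L, 2L), c(1L, 2L, 4L), c(1L, 4L, 3L), c(2L, 3L, 4L))
  tri_mesh(v, f, source_id = "tetra")
}

as_cloud <- function(points, source_id = "manual", seed = 0L,
                     normalized = FALSE) {
  structure(list(points = as.matrix(points), n_points = nrow(points),
                 provenance = list(source_id = source_id, seed = seed,
                                   normalized = normalized)),
            class = "point_cloud")
}

# A full-marks sheet with optional tweaks.
max_sheet <- function(case_id = "max", ...) {
  r <- rubric_criteria()
  vals <- setNames(pmax(r$max, 0), r$key)
  tweaks <- list(...)
  vals[names(tweaks)] <- unlist(tweaks)
  score_sheet(case_id, vals)
}

random_sheet <- function(case_id = "rand") {
  r <- rubric_criteria()
  vals <- setNames(round_to_half(runif(nrow(r), r$min, r$max)), r$key)
  score_sheet(case_id, vals, examiner = TRUE)
}

round_to_half <- function(x) round(x * 2) / 2

# Compact network settings used throughout the tests.
tiny_config <- function(n_points = 256L, seed = 42L) {
  model_config(n_points = n_points, point_widths = c(8L, 16L),
               head_widths = c(16L,  8L), seed = seed)
}

small_cohort <- function(n = 8L, seed = 5L, out_dir = NULL) {
  generate_cohort(n = n, seed = seed, out_dir = out_dir)
}
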