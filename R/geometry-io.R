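#' Triangle mesh container
#'
#' Bundles vertices and triangular faces of a surface scan (or synthetic
#' stand-in) with a source label. Faces are stored 1-based, the R convention;
#' OBJ's 1-based (and negative, relative) indices are resolved on read.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param source_id character label carried into point-cloud provenance.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, source_id = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop_named("prepscore_bad_mesh", "vertices must have 3 columns")
  if (ncol(faces) != 3L) stop_named("prepscore_bad_mesh", "faces must have 3 columns")
  if (nrow(faces) < 1L) stop_named("prepscore_no_faces", "mesh has no faces")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop_named("prepscore_face_index", "face index out of vertex range")
  structure(list(vertices = vertices, faces = faces,
                 source_id = as.character(source_id)),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh '%s': %d vertices, %d faces>\n",
              x$source_id, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Per-face areas via the cross-product norm.
face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Read a Wavefront OBJ surface mesh
#'
#' Supports `v` and `f` records; `vn`/`vt`/`mtllib`/`usemtl`/`g`/`o`/`s` and
#' comments are ignored. Polygonal faces are fan-triangulated. Negative OBJ
#' indices are resolved relative to the vertex count seen so far, per the OBJ
#' convention. Zero-area faces are dropped with a message.
#'
#' @param path path to an OBJ file.
#' @param source_id label recorded on the mesh; defaults to the file name.
#' @return A [tri_mesh()].
#' @export
read_obj <- function(path, source_id = NULL) {
  if (!is.character(path) || length(path) != 1L || !nzchar(path) || !file.exists(path))
    stop_named("prepscore_missing_file", sprintf("OBJ file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[ \t]+")
  keys <- vapply(toks, `[[`, "", 1L)

  vlines <- toks[keys == "v"]
  if (length(vlines) == 0L)
    stop_named("prepscore_no_faces", sprintf("no vertices in '%s'", path))
  verts <- t(vapply(vlines, function(t) as.numeric(t[2:4]), numeric(3)))
  if (anyNA(verts)) stop_named("prepscore_bad_mesh", "unparsable vertex record")

  # Vertex count at the time each face line is seen, for negative indices.
  is_v <- keys == "v"
  n_before <- cumsum(is_v)
  face_rows <- which(keys == "f")
  if (length(face_rows) == 0L)
    stop_named("prepscore_no_faces", sprintf("no faces in '%s'", path))

  tri <- vector("list", length(face_rows))
  for (i in seq_along(face_rows)) {
    row <- face_rows[i]
    fields <- toks[[row]][-1L]
    # "12/5/7" -> vertex index is the first slash-field
    idx <- as.integer(vapply(strsplit(fields, "/", fixed = TRUE), `[[`, "", 1L))
    if (anyNA(idx)) stop_named("prepscore_bad_mesh", "unparsable face record")
    neg <- idx < 0L
    idx[neg] <- n_before[row] + idx[neg] + 1L
    if (any(idx < 1L) || any(idx > nrow(verts)))
      stop_named("prepscore_face_index",
                 sprintf("face index out of range on line %d of '%s'", row, path))
    if (length(idx) < 3L) stop_named("prepscore_bad_mesh", "face with fewer than 3 vertices")
    tri[[i]] <- cbind(idx[1L], idx[2:(length(idx) - 1L)], idx[3:length(idx)])
  }
  faces <- do.call(rbind, tri)

  mesh <- structure(list(vertices = verts, faces = faces,
                         source_id = source_id %||% basename(path)),
                    class = "tri_mesh")
  areas <- face_areas(mesh)
  n_degen <- sum(areas <= 0)
  if (n_degen > 0L) {
    message(sprintf("read_obj: dropped %d degenerate (zero-area) face(s)", n_degen))
    mesh$faces <- mesh$faces[areas > 0, , drop = FALSE]
  }
  if (nrow(mesh$faces) == 0L)
    stop_named("prepscore_no_faces", sprintf("no non-degenerate faces in '%s'", path))
  mesh
}

#' Write a mesh as Wavefront OBJ
#'
#' @param mesh a [tri_mesh()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", mesh$source_id), con)
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1L], mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1L], mesh$faces[, 2L], mesh$faces[, 3L]), con)
  invisible(path)
}

#' Sampler configuration
#'
#' @param n_points number of surface points to draw (default 100000, the
#'   resolution every training and inference path uses).
#' @param seed integer seed; the sampler derives a per-mesh stream from
#'   `(seed, source_id)` so results do not depend on batch order.
#' @param normalization normalization convention; only `"unit_sphere"`.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_points = 100000L, seed = 7L,
                           normalization = "unit_sphere") {
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 1L)
    stop_named("prepscore_bad_config", "n_points must be a positive integer")
  normalization <- match.arg(normalization)
  structure(list(n_points = n_points, seed = as.integer(seed),
                 normalization = normalization),
            class = "sampler_config")
}

#' Sample a deterministic point cloud from a mesh surface
#'
#' Draws `n_points` points by area-weighted face selection followed by uniform
#' barycentric placement. The generator is seeded from the config seed and the
#' mesh `source_id`, so identical `(mesh, config)` give bit-identical clouds.
#'
#' @param mesh a [tri_mesh()].
#' @param config a [sampler_config()].
#' @return An object of class `point_cloud` with fields `points` (n x 3),
#'   `n_points` and `provenance`.
#' @export
sample_point_cloud <- function(mesh, config = sampler_config()) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(config, "sampler_config"))
  areas <- face_areas(mesh)
  total <- sum(areas)
  if (!is.finite(total) || total <= 0)
    stop_named("prepscore_zero_area", "mesh has zero total surface area")
  n <- config$n_points
  v <- mesh$vertices
  f <- mesh$faces
  pts <- with_seed(derive_seed(config$seed, mesh$source_id), {
    fi <- sample.int(nrow(f), n, replace = TRUE, prob = areas / total)
    r1 <- sqrt(runif(n))
    r2 <- runif(n)
    u <- 1 - r1
    w <- r1 * r2
    s <- r1 * (1 - r2)
    a <- v[f[fi, 1L], , drop = FALSE]
    b <- v[f[fi, 2L], , drop = FALSE]
    cc <- v[f[fi, 3L], , drop = FALSE]
    u * a + s * b + w * cc
  })
  structure(list(points = pts, n_points = n,
                 provenance = list(source_id = mesh$source_id,
                                   seed = config$seed,
                                   normalized = FALSE)),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud '%s': %d points, seed %d, %s>\n",
              x$provenance$source_id, x$n_points, x$provenance$seed,
              if (isTRUE(x$provenance$normalized)) "normalized" else "raw"))
  invisible(x)
}

#' Normalize a point cloud to the unit sphere
#'
#' Translates the centroid to the origin and divides all coordinates by the
#' maximum centroid-to-point distance, so every cloud occupies the unit ball
#' with at least one point on its surface. Scores computed downstream are
#' therefore invariant to rigid translation and uniform scaling of the scan.
#'
#' @param pc a `point_cloud`.
#' @return The normalized `point_cloud` (provenance flag set).
#' @export
normalize_point_cloud <- function(pc) {
  stopifnot(inherits(pc, "point_cloud"))
  ctr <- colMeans(pc$points)
  centered <- sweep(pc$points, 2L, ctr)
  r <- sqrt(max(rowSums(centered^2)))
  if (!is.finite(r) || r <= 0)
    stop_named("prepscore_degenerate_cloud",
               "all points coincide; cannot rescale to unit sphere")
  pc$points <- centered / r
  pc$provenance$normalized <- TRUE
  pc
}

#' Write / read a point cloud as ascii PLY
#'
#' Plain-text PLY with provenance (`source_id`, `seed`, normalization flag)
#' stored in header comments and recovered on read.
#'
#' @param pc a `point_cloud`.
#' @param path file path.
#' @return `write_point_cloud` returns `path` invisibly; `read_point_cloud`
#'   returns a `point_cloud`.
#' @export
write_point_cloud <- function(pc, path) {
  stopifnot(inherits(pc, "point_cloud"))
  if (!is.character(path) || length(path) != 1L || !nzchar(path))
    stop_named("prepscore_io", "empty output path")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply",
    "format ascii 1.0",
    sprintf("comment source_id %s", pc$provenance$source_id),
    sprintf("comment seed %d", pc$provenance$seed),
    sprintf("comment normalized %d", as.integer(isTRUE(pc$provenance$normalized))),
    sprintf("element vertex %d", pc$n_points),
    "property double x",
    "property double y",
    "property double z",
    "end_header"), con)
  writeLines(sprintf("%.10g %.10g %.10g",
                     pc$points[, 1L], pc$points[, 2L], pc$points[, 3L]), con)
  invisible(path)
}

#' @rdname write_point_cloud
#' @export
read_point_cloud <- function(path) {
  if (!file.exists(path))
    stop_named("prepscore_missing_file", sprintf("PLY file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || lines[1L] != "ply" || !grepl("ascii", lines[2L]))
    stop_named("prepscore_bad_ply", "not an ascii PLY file")
  end <- match("end_header", lines)
  if (is.na(end)) stop_named("prepscore_bad_ply", "PLY header not terminated")
  header <- lines[seq_len(end)]
  nvert_line <- grep("^element vertex ", header, value = TRUE)
  if (length(nvert_line) != 1L) stop_named("prepscore_bad_ply", "missing vertex element")
  n <- as.integer(sub("^element vertex ", "", nvert_line))
  grab <- function(key, default) {
    m <- grep(paste0("^comment ", key, " "), header, value = TRUE)
    if (length(m) == 1L) sub(paste0("^comment ", key, " "), "", m) else default
  }
  body <- lines[(end + 1L):length(lines)]
  body <- body[nzchar(body)]
  if (length(body) != n) stop_named("prepscore_bad_ply", "vertex count mismatch")
  pts <- matrix(scan(text = body, quiet = TRUE), ncol = 3L, byrow = TRUE)
  structure(list(points = pts, n_points = n,
                 provenance = list(source_id = grab("source_id", "unknown"),
                                   seed = as.integer(grab("seed", "0")),
                                   normalized = grab("normalized", "0") == "1")),
            class = "point_cloud")
}

# One-call preprocessing used by training, evaluation and single-case scoring:
# OBJ/mesh -> sampled cloud -> unit-sphere normalization.
#' Preprocess a mesh into the network's input representation
#'
#' @param mesh a `tri_mesh` or a path to an OBJ file.
#' @param config a [sampler_config()].
#' @return A normalized `point_cloud`.
#' @export
preprocess_mesh <- function(mesh, config = sampler_config()) {
  if (is.character(mesh)) mesh <- read_obj(mesh)
  normalize_point_cloud(sample_point_cloud(mesh, config))
}
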