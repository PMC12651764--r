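# OBJ reading, deterministic surface sampling, unit-sphere normalization,
# and PLY round-tripping.

test_that("read_obj parses minimal, quad and annotated OBJ files", {
  m <- read_obj(write_obj_text(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3")))
  expect_equal(nrow(m$vertices), 3L)
  expect_equal(nrow(m$faces), 1L)

  quad <- read_obj(write_obj_text(c("v 0 0 0", "v 1 0 0", "v 1 1 0",
                                    "v 0 1 0", "f 1 2 3 4")))
  expect_equal(nrow(quad$faces), 2L)
  expect_equal(quad$faces, rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)),
               ignore_attr = TRUE)

  plain <- c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3")
  annotated <- c("# comment", "o tooth", "vn 0 0 1", "vt 0.1 0.2",
                 "usemtl enamel", plain, "s off")
  m1 <- read_obj(write_obj_text(plain))
  m2 <- read_obj(write_obj_text(annotated))
  expect_equal(m1$vertices, m2$vertices)
  expect_equal(m1$faces, m2$faces)

  # slashed face records and negative (relative) indices
  m3 <- read_obj(write_obj_text(c("v 0 0 0", "v 1 0 0", "v 0 1 0",
                                  "f 1/1/1 2/2/2 3/3/3")))
  expect_equal(m3$faces, m1$faces)
  m4 <- read_obj(write_obj_text(c("v 0 0 0", "v 1 0 0", "v 0 1 0",
                                  "f -3 -2 -1")))
  expect_equal(m4$faces, m1$faces)
})

test_that("read_obj failure modes raise distinct named errors", {
  expect_error(read_obj(tempfile(fileext = ".obj")),
               class = "prepscore_missing_file")
  expect_error(read_obj(write_obj_text(c("v 0 0 0", "v 1 0 0"))),
               class = "prepscore_no_faces")
  expect_error(read_obj(write_obj_text(c("v 0 0 0", "v 1 0 0", "v 0 1 0",
                                         "f 1 2 7"))),
               class = "prepscore_face_index")
  # zero-area faces are dropped with a message, not an error
  expect_message(
    m <- read_obj(write_obj_text(c("v 0 0 0", "v 1 0 0", "v 0 1 0",
                                   "f 1 2 3", "f 1 1 2"))),
    "degenerate")
  expect_equal(nrow(m$faces), 1L)
  # a mesh reduced to only degenerate faces is refused
  expect_error(
    suppressMessages(
      read_obj(write_obj_text(c("v 0 0 0", "v 1 0 0", "v 0 1 0",
                                "f 1 1 2")))),
    class = "prepscore_no_faces")
})

test_that("sampling is supported on the surface, area-weighted, and exact in count", {
  mesh <- single_triangle_mesh()
  pc <- sample_point_cloud(mesh, sampler_config(n_points = 500, seed = 3))
  expect_equal(nrow(pc$points), 500L)
  # barycentric containment for the single face
  A <- mesh$vertices[1, ]; B <- mesh$vertices[2, ]; C <- mesh$vertices[3, ]
  M <- cbind(B - A, C - A)
  uv <- t(qr.solve(M[1:2, ], t(pc$points[, 1:2]) - A[1:2]))
  expect_true(all(uv > -1e-9))
  expect_true(all(rowSums(uv) < 1 + 1e-9))
  expect_true(all(abs(pc$points[, 3]) < 1e-12))

  # area-weighted face selection: 9:1 areas, binomial 3-sigma oracle
  n <- 100000
  pc2 <- sample_point_cloud(two_plane_mesh(), sampler_config(n, seed = 11))
  frac_small <- mean(pc2$points[, 3] > 0.5)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(frac_small - 0.1), 3 * se)
})

test_that("per-face counts match area proportions on a small mesh", {
  mesh <- tetra_mesh()
  areas <- prepscore:::face_areas(mesh)
  probs <- areas / sum(areas)
  n <- 20000
  pc <- sample_point_cloud(mesh, sampler_config(n, seed = 9))
  # assign each point to the nearest face plane
  v <- mesh$vertices
  dists <- sapply(seq_len(nrow(mesh$faces)), function(k) {
    a <- v[mesh$faces[k, 1], ]; b <- v[mesh$faces[k, 2], ]; c3 <- v[mesh$faces[k, 3], ]
    nrm <- c((b - a)[2] * (c3 - a)[3] - (b - a)[3] * (c3 - a)[2],
             (b - a)[3] * (c3 - a)[1] - (b - a)[1] * (c3 - a)[3],
             (b - a)[1] * (c3 - a)[2] - (b - a)[2] * (c3 - a)[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    abs((pc$points - matrix(a, n, 3, byrow = TRUE)) %*% nrm)
  })
  counts <- tabulate(apply(dists, 1, which.min), nbins = 4)
  for (k in 1:4)
    expect_lt(abs(counts[k] - n * probs[k]),
              3 * sqrt(n * probs[k] * (1 - probs[k])))
})

test_that("sampling is a pure function of mesh and config", {
  p <- prep_params(mesh_resolution = 2L)
  m <- generate_mesh(p)
  cfg <- sampler_config(n_points = 4096, seed = 21)
  expect_identical(sample_point_cloud(m, cfg)$points,
                   sample_point_cloud(m, cfg)$points)
  # a different seed moves the points
  expect_false(identical(sample_point_cloud(m, cfg)$points,
                         sample_point_cloud(m, sampler_config(4096, 22))$points))
  expect_error(sampler_config(n_points = 0), class = "prepscore_bad_config")
})

test_that("normalization centres, rescales, and is idempotent and similarity-invariant", {
  pc <- as_cloud(rbind(c(0, 0, 0), c(2, 0, 0)))
  out <- normalize_point_cloud(pc)
  expect_equal(out$points, rbind(c(-1, 0, 0), c(1, 0, 0)), ignore_attr = TRUE)
  expect_true(out$provenance$normalized)

  m <- generate_mesh(prep_params(mesh_resolution = 2L))
  cfg <- sampler_config(2048, seed = 5)
  base <- normalize_point_cloud(sample_point_cloud(m, cfg))
  expect_lt(max(abs(normalize_point_cloud(base)$points - base$points)), 1e-9)

  moved <- m
  moved$vertices <- 3 * m$vertices + matrix(c(5, 5, 5), nrow(m$vertices), 3,
                                            byrow = TRUE)
  alt <- normalize_point_cloud(sample_point_cloud(moved, cfg))
  expect_lt(max(abs(alt$points - base$points)), 1e-6)

  expect_error(normalize_point_cloud(as_cloud(rbind(c(1, 1, 1), c(1, 1, 1)))),
               class = "prepscore_degenerate_cloud")
})

test_that("PLY round-trip preserves coordinates and provenance", {
  m <- generate_mesh(prep_params(mesh_resolution = 2L))
  pc <- normalize_point_cloud(
    sample_point_cloud(m, sampler_config(512, seed = 13)))
  path <- tempfile(fileext = ".ply")
  write_point_cloud(pc, path)
  back <- read_point_cloud(path)
  expect_lt(max(abs(back$points - pc$points)), 1e-6)
  expect_identical(back$provenance$source_id, pc$provenance$source_id)
  expect_identical(back$provenance$seed, pc$provenance$seed)
  expect_true(back$provenance$normalized)

  expect_error(write_point_cloud(pc, ""), class = "prepscore_io")
  bad <- tempfile(fileext = ".ply")
  writeLines(c("not", "a ply"), bad)
  expect_error(read_point_cloud(bad), class = "prepscore_bad_ply")
})
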