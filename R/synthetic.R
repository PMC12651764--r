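# Synthetic molar-like preparation meshes with known ground-truth scores.
#
# Geometry is a radially displaced subdivided icosphere (a height field over
# the sphere): cusps are smooth bumps, cavities smooth Gaussian depressions,
# residual caries a smaller bump on the cavity floor, adjacent teeth separate
# displaced spheres offset to realize the requested clearance. No boolean
# solid operations, so every surface is closed and construction is exactly
# deterministic in the parameters.

# Unit icosphere: icosahedron subdivided `level` times, vertices on the
# unit sphere, outward-oriented faces.
icosphere <- function(level = 4L) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(level)) {
    edge_mid <- new.env(hash = TRUE)
    verts <- v
    nf <- nrow(f)
    newf <- matrix(0L, nf * 4L, 3L)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      m <- edge_mid[[key]]
      if (!is.null(m)) return(m)
      p <- (verts[i, ] + verts[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      verts <<- rbind(verts, p)
      m <- nrow(verts)
      edge_mid[[key]] <- m
      m
    }
    for (k in seq_len(nf)) {
      a <- f[k, 1L]; b <- f[k, 2L]; cc <- f[k, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[4L * k - 3L, ] <- c(a, ab, ca)
      newf[4L * k - 2L, ] <- c(b, bc, ab)
      newf[4L * k - 1L, ] <- c(cc, ca, bc)
      newf[4L * k, ] <- c(ab, bc, ca)
    }
    v <- verts
    f <- newf
  }
  list(dirs = v, faces = f)
}

# Cache the subdivided spheres; they are pure functions of the level.
.icosphere_cache <- new.env(parent = emptyenv())
icosphere_cached <- function(level) {
  key <- as.character(level)
  if (is.null(.icosphere_cache[[key]]))
    .icosphere_cache[[key]] <- icosphere(level)
  .icosphere_cache[[key]]
}

#' Parameters of a synthetic cavity preparation
#'
#' Describes a molar-like tooth (tooth 46 stand-in) carrying one occlusal and
#' one mesial lesion, the geometry of their preparation, and the preparation
#' faults the rubric penalizes. All lengths in mm. The convention is +z
#' occlusal, +x mesial (toward the adjacent tooth), +/-y buccal/lingual.
#'
#' @param seed integer; only consumed by the optional vertex jitter.
#' @param base_radius tooth crown radius.
#' @param cusp_amplitude height of the four cusp bumps.
#' @param occlusal_cavity list(radius, depth): Gaussian depression at the
#'   occlusal center.
#' @param mesial_box list(width, depth, gingival_margin): the proximal box on
#'   the mesial face.
#' @param clearance_buccal,clearance_lingual,clearance_gingival gaps (mm)
#'   between the proximal box walls and the adjacent tooth surface.
#' @param residual_caries_fraction fraction of carious material left behind,
#'   realized as a bump on the cavity floors.
#' @param isthmus_thickness residual ridge thickness between the two cavities.
#' @param undermined_extent fraction of the occlusal margin left unsupported,
#'   realized as a shallow rim groove.
#' @param adjacent_damage_depth iatrogenic depression on the adjacent tooth,
#'   in [0, 2] mm.
#' @param pulp_exposure logical; realized as a narrow deep central pit.
#' @param include_adjacent_teeth logical; add mesial/distal neighbours.
#' @param mesh_resolution icosphere subdivision level.
#' @param jitter_sd optional Gaussian vertex jitter (mm); 0 disables it.
#' @return An object of class `prep_params`.
#' @export
prep_params <- function(seed = 1L, base_radius = 5, cusp_amplitude = 0.6,
                        occlusal_cavity = list(radius = 1.4, depth = 1.5),
                        mesial_box = list(width = 2.5, depth = 1.4,
                                          gingival_margin = 1.0),
                        clearance_buccal = 0.6, clearance_lingual = 0.6,
                        clearance_gingival = 0.6,
                        residual_caries_fraction = 0,
                        isthmus_thickness = 1.2,
                        undermined_extent = 0,
                        adjacent_damage_depth = 0,
                        pulp_exposure = FALSE,
                        include_adjacent_teeth = TRUE,
                        mesh_resolution = 4L,
                        jitter_sd = 0) {
  p <- list(seed = as.integer(seed), base_radius = base_radius,
            cusp_amplitude = cusp_amplitude, occlusal_cavity = occlusal_cavity,
            mesial_box = mesial_box, clearance_buccal = clearance_buccal,
            clearance_lingual = clearance_lingual,
            clearance_gingival = clearance_gingival,
            residual_caries_fraction = residual_caries_fraction,
            isthmus_thickness = isthmus_thickness,
            undermined_extent = undermined_extent,
            adjacent_damage_depth = adjacent_damage_depth,
            pulp_exposure = isTRUE(pulp_exposure),
            include_adjacent_teeth = isTRUE(include_adjacent_teeth),
            mesh_resolution = as.integer(mesh_resolution),
            jitter_sd = jitter_sd)
  stopifnot(p$base_radius > 0, p$cusp_amplitude >= 0,
            p$occlusal_cavity$radius >= 0, p$occlusal_cavity$depth >= 0,
            p$mesial_box$width >= 0, p$mesial_box$depth >= 0,
            p$residual_caries_fraction >= 0, p$residual_caries_fraction <= 1,
            p$undermined_extent >= 0, p$undermined_extent <= 1,
            p$adjacent_damage_depth >= 0, p$adjacent_damage_depth <= 2,
            p$isthmus_thickness >= 0, p$jitter_sd >= 0)
  max_cut <- p$occlusal_cavity$depth + if (p$pulp_exposure) 1.5 else 0
  if (max(max_cut, p$mesial_box$depth) >= p$base_radius)
    stop_named("prepscore_bad_params",
               "cavity depth reaches or exceeds the tooth radius (self-intersecting)")
  structure(p, class = "prep_params")
}

# Gaussian depression over geodesic distance (mm) from a center direction.
gauss_cut <- function(dirs, center, radius_mm, base_radius, depth) {
  if (depth == 0 || radius_mm <= 0) return(numeric(nrow(dirs)))
  cosang <- pmin(1, pmax(-1, drop(dirs %*% center)))
  g <- base_radius * acos(cosang)
  depth * exp(-(g / radius_mm)^2)
}

# Radial displacement field of the prepared tooth, per unit direction.
prep_radius_field <- function(dirs, p) {
  r <- rep(p$base_radius, nrow(dirs))
  # four cusps on a ring 40 degrees off the occlusal pole
  alpha <- 40 * pi / 180
  for (phi in c(45, 135, 225, 315) * pi / 180) {
    cusp <- c(sin(alpha) * cos(phi), sin(alpha) * sin(phi), cos(alpha))
    r <- r + gauss_cut(dirs, cusp, 0.35 * p$base_radius, p$base_radius,
                       p$cusp_amplitude)
  }
  occ_center <- c(0, 0, 1)
  mes_center <- c(1, 0, 0.12)
  mes_center <- mes_center / sqrt(sum(mes_center^2))
  occ <- p$occlusal_cavity
  mes <- p$mesial_box
  res <- p$residual_caries_fraction
  if (occ$depth > 0) {
    r <- r - gauss_cut(dirs, occ_center, occ$radius, p$base_radius, occ$depth)
    # residual caries: a bump left on the cavity floor
    r <- r + gauss_cut(dirs, occ_center, 0.4 * occ$radius, p$base_radius,
                       res * occ$depth)
    # undermined enamel: shallow groove at the cavity rim
    if (p$undermined_extent > 0) {
      cosang <- pmin(1, pmax(-1, drop(dirs %*% occ_center)))
      g <- p$base_radius * acos(cosang)
      r <- r - 0.3 * p$undermined_extent *
        exp(-((g - occ$radius) / (0.3 * occ$radius))^2)
    }
  }
  if (mes$depth > 0) {
    half_w <- mes$width / 2
    r <- r - gauss_cut(dirs, mes_center, half_w, p$base_radius, mes$depth)
    r <- r + gauss_cut(dirs, mes_center, 0.4 * half_w, p$base_radius,
                       res * mes$depth)
  }
  # a thin isthmus erodes the ridge between the two cavities
  if (occ$depth > 0 && mes$depth > 0 && p$isthmus_thickness < 1.5) {
    saddle <- occ_center + mes_center
    saddle <- saddle / sqrt(sum(saddle^2))
    r <- r - gauss_cut(dirs, saddle, 0.6, p$base_radius,
                       0.6 * (1.5 - p$isthmus_thickness))
  }
  if (p$pulp_exposure)
    r <- r - gauss_cut(dirs, occ_center, 0.35, p$base_radius,
                       if (occ$depth > 0) 1.5 else 1.5 + occ$depth)
  r
}

#' Generate a synthetic preparation mesh from parameters
#'
#' Deterministic in `params`: two calls give identical vertex arrays. The
#' prepared tooth and (optionally) its mesial and distal neighbours are each
#' closed displaced spheres combined into one mesh; the mesial neighbour is
#' offset so its closest approach to the prepared crown equals the smallest
#' requested clearance, and carries the iatrogenic damage depression on the
#' face toward the preparation.
#'
#' @param params a [prep_params()].
#' @return A [tri_mesh()] with `source_id` `"synthetic"`.
#' @export
generate_mesh <- function(params) {
  stopifnot(inherits(params, "prep_params"))
  p <- params
  ico <- icosphere_cached(p$mesh_resolution)
  dirs <- ico$dirs
  r <- prep_radius_field(dirs, p)
  verts <- dirs * r
  faces <- ico$faces
  if (p$include_adjacent_teeth) {
    adj_radius <- 0.8 * p$base_radius
    gap <- min(p$clearance_buccal, p$clearance_lingual, p$clearance_gingival)
    # mesial neighbour, with damage facing the preparation
    facing <- c(-1, 0, 0)
    dmg <- p$adjacent_damage_depth
    r_adj <- adj_radius - gauss_cut(dirs, facing, 1.0, adj_radius, dmg)
    offset_m <- c(p$base_radius + gap + adj_radius, 0, 0)
    v_m <- sweep(dirs * r_adj, 2L, offset_m, "+")
    # distal neighbour at light natural contact
    offset_d <- c(-(p$base_radius + 0.2 + adj_radius), 0, 0)
    v_d <- sweep(dirs * adj_radius, 2L, offset_d, "+")
    nv <- nrow(verts)
    faces <- rbind(faces, ico$faces + nv, ico$faces + nv + nrow(v_m))
    verts <- rbind(verts, v_m, v_d)
  }
  if (p$jitter_sd > 0) {
    verts <- verts + with_seed(derive_seed(p$seed, "jitter"),
                               matrix(rnorm(length(verts), sd = p$jitter_sd),
                                      ncol = 3L))
  }
  tri_mesh(verts, faces, source_id = "synthetic")
}

#' Enclosed volume of a closed triangle mesh
#'
#' Signed-tetrahedron (divergence theorem) sum; for a mesh of several closed
#' components the component volumes add.
#'
#' @param mesh a [tri_mesh()].
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  cc <- v[f[, 3L], , drop = FALSE]
  det6 <- a[, 1L] * (b[, 2L] * cc[, 3L] - b[, 3L] * cc[, 2L]) -
    a[, 2L] * (b[, 1L] * cc[, 3L] - b[, 3L] * cc[, 1L]) +
    a[, 3L] * (b[, 1L] * cc[, 2L] - b[, 2L] * cc[, 1L])
  abs(sum(det6)) / 6
}

#' Occlusal preparation-depth proxy of a mesh
#'
#' A model-free geometric feature: the median crown radius in a polar band
#' (20-45 degrees off the occlusal axis) minus the minimum radius inside a
#' 15-degree polar cone. For a prepared tooth centred at the origin this
#' measures the depth of material removed at the occlusal cavity floor
#' (residual caries raises the floor and shrinks it). Used to check that the
#' synthetic scoring task carries geometric signal rather than noise;
#' adjacent teeth sit near the equator and do not enter either region.
#'
#' @param mesh a [tri_mesh()] with the prepared tooth centred at the origin
#'   and the occlusal surface toward +z.
#' @return Depth proxy in mm.
#' @export
occlusal_depth_proxy <- function(mesh) {
  v <- mesh$vertices
  r <- sqrt(rowSums(v^2))
  ang <- acos(pmin(1, pmax(-1, v[, 3L] / pmax(r, 1e-12))))
  cone <- ang < 15 * pi / 180
  band <- ang > 20 * pi / 180 & ang < 45 * pi / 180
  if (!any(cone) || !any(band))
    stop_named("prepscore_bad_input", "mesh has no vertices in the occlusal regions")
  stats::median(r[band]) - min(r[cone])
}

round_half <- function(x) round(x * 2) / 2

clearance_points <- function(gap) {
  ifelse(gap >= 0.5, 2, ifelse(gap >= 0.25, 1, 0))
}

#' Map preparation parameters to their ground-truth score sheet
#'
#' The deterministic geometry-to-rubric map: clearance bands at 0.25/0.5 mm,
#' caries removal proportional to the material actually removed, isthmus
#' bands at 0.5/1.0 mm, cusp preservation from the cavity footprint, enamel
#' support proportional to the undermined extent, and a piecewise-linear
#' damage deduction (0 to -2 points below 1 mm, -2 to -4 points at 1-2 mm).
#' These cutoffs are package constants standing in for the judgement
#' examiners apply to real preparations.
#'
#' @param params a [prep_params()].
#' @return A [score_sheet()] (examiner-grade, half-point values).
#' @export
scoring_map <- function(params) {
  stopifnot(inherits(params, "prep_params"))
  p <- params
  dmg <- p$adjacent_damage_depth
  damage_pts <- if (dmg == 0) 0
  else if (dmg < 1) -2 * dmg
  else -(2 + 2 * (dmg - 1))
  # cusps sit ~40 degrees off the pole; untouched if the cavity footprint
  # (taken as 1.5 Gaussian radii) stays clear of them
  cusp_dist <- p$base_radius * 40 * pi / 180
  occ_pres <- as.numeric(1.5 * p$occlusal_cavity$radius < cusp_dist)
  vals <- c(
    clearance_buccal = clearance_points(p$clearance_buccal),
    clearance_lingual = clearance_points(p$clearance_lingual),
    clearance_gingival = clearance_points(p$clearance_gingival),
    preservation_between = if (p$isthmus_thickness >= 1.0) 2
      else if (p$isthmus_thickness >= 0.5) 1 else 0,
    occlusal_preservation = occ_pres,
    caries_removal = round_half(9 * (1 - p$residual_caries_fraction)),
    no_undermined_enamel = round_half(2 * (1 - p$undermined_extent)),
    adjacent_damage = round_half(damage_pts)
  )
  score_sheet(sprintf("prep_seed_%d", p$seed), vals,
              pulp_exposure = p$pulp_exposure, examiner = TRUE)
}

# Default cohort parameter distribution. A latent "operator skill" q in [0,1]
# drives the fault magnitudes jointly, the way real student cohorts couple
# faults; top-skill draws reach the full 20 points and low-skill draws fall
# to 8 or below, matching the spread seen in examiner-scored cohorts.
draw_params <- function(i, q) {
  prep_params(
    seed = i,
    occlusal_cavity = list(radius = runif(1, 1.2, 1.6),
                           depth = runif(1, 1.3, 1.7)),
    mesial_box = list(width = runif(1, 2.2, 2.8), depth = runif(1, 1.2, 1.6),
                      gingival_margin = runif(1, 0.8, 1.2)),
    clearance_buccal = max(0, q * 0.7 + runif(1, -0.15, 0.15)),
    clearance_lingual = max(0, q * 0.7 + runif(1, -0.15, 0.15)),
    clearance_gingival = max(0, q * 0.7 + runif(1, -0.15, 0.15)),
    residual_caries_fraction = max(0, 0.55 - q) * runif(1, 0.5, 1),
    isthmus_thickness = 0.3 + q * 1.1 + runif(1, -0.1, 0.1),
    undermined_extent = max(0, 0.6 - q) * runif(1),
    adjacent_damage_depth = if (runif(1) < 0.3 * (1 - q)) runif(1, 0.2, 1.8) else 0,
    pulp_exposure = FALSE
  )
}

#' Generate a cohort of synthetic scored preparations
#'
#' Draws case parameters from the default skill-driven distribution with a
#' seeded generator, scores each case with [scoring_map()], and splits the
#' cohort into train/test folders by a seeded shuffle. Defaults mirror the
#' study design this package emulates: 30 cases, 20 training and 10 test.
#'
#' @param n cohort size.
#' @param seed integer seed controlling both parameter draws and the split.
#' @param n_test number of held-out test cases.
#' @param out_dir optional directory; when given, writes `train/` and `test/`
#'   folders of `<case_id>.obj` + `<case_id>.json` pairs plus `manifest.csv`.
#' @return A list of `synthetic_case` objects: `case_id`, `params`, `mesh`,
#'   `sheet`, `split`, and (when written) `mesh_path`/`label_path`.
#' @export
generate_cohort <- function(n = 30L, seed = 1L, n_test = max(1L, round(n / 3)),
                            out_dir = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop_named("prepscore_bad_config", "n must be >= 1")
  cases <- with_seed(derive_seed(seed, "cohort"), {
    qs <- runif(n)
    lapply(seq_len(n), function(i) {
      pr <- draw_params(i, qs[i])
      list(case_id = sprintf("case_%03d", i), params = pr)
    })
  })
  split <- rep("train", n)
  split[with_seed(derive_seed(seed, "split"), sample.int(n, min(n_test, n)))] <- "test"
  cases <- lapply(seq_len(n), function(i) {
    cs <- cases[[i]]
    mesh <- generate_mesh(cs$params)
    mesh$source_id <- cs$case_id
    sheet <- scoring_map(cs$params)
    sheet$case_id <- cs$case_id
    structure(list(case_id = cs$case_id, params = cs$params, mesh = mesh,
                   sheet = sheet, split = split[i]),
              class = "synthetic_case")
  })
  if (!is.null(out_dir)) {
    for (sub in c("train", "test"))
      dir.create(file.path(out_dir, sub), recursive = TRUE, showWarnings = FALSE)
    rows <- lapply(cases, function(cs) {
      mesh_path <- file.path(out_dir, cs$split, paste0(cs$case_id, ".obj"))
      label_path <- file.path(out_dir, cs$split, paste0(cs$case_id, ".json"))
      write_obj(cs$mesh, mesh_path)
      write_label_json(cs$sheet, label_path)
      data.frame(case_id = cs$case_id, split = cs$split,
                 total = total_score(cs$sheet),
                 residual_caries_fraction = cs$params$residual_caries_fraction,
                 adjacent_damage_depth = cs$params$adjacent_damage_depth,
                 stringsAsFactors = FALSE)
    })
    manifest <- do.call(rbind, rows)
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    for (i in seq_along(cases)) {
      cases[[i]]$mesh_path <- file.path(out_dir, cases[[i]]$split,
                                        paste0(cases[[i]]$case_id, ".obj"))
      cases[[i]]$label_path <- file.path(out_dir, cases[[i]]$split,
                                         paste0(cases[[i]]$case_id, ".json"))
    }
  }
  cases
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("<synthetic_case '%s' [%s]: total %g>\n",
              x$case_id, x$split, total_score(x$sheet)))
  invisible(x)
}
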