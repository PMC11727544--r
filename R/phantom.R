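# Synthetic tractogram phantoms.
#
# The phantom emulates, in an MNI-like 180 x 216 x 180 mm space (1 mm
# isotropic, x = left-right with midline at x = 90, y = posterior-anterior,
# z = inferior-superior), the four association bundles studied in clinical
# virtual dissection -- the arcuate fasciculus (AF) arching around the
# Sylvian fissure, its indirect anterior (fronto-parietal) and posterior
# (temporo-parietal) segments, and the long inferior fronto-occipital
# fasciculus (IFOF) funnelled through a narrow stem -- plus the recurrent
# artefact streamline populations that contaminate ROI-based segmentations:
# AF-like streamlines ending in the parietal lobe, short U-fibers near the
# inclusion ROIs, IFOF-like streamlines looping back dorsally, vertical
# projection-like streamlines, commissural crossers, and background clutter.
# All bundles live in the left half of the grid (the "healthy hemisphere").
# Every streamline carries a ground-truth label so downstream segmentation
# engines can be scored without clinical data.

PHANTOM_MIDLINE_X <- 90

# Centerline control points (world mm). Chosen so that each bundle crosses
# its inclusion ROIs with >= ~12 mm of margin against the transverse
# dispersion, and stays >= ~10 mm clear of every exclusion ROI of its own
# recipe (see default_recipes()).
phantom_centerlines <- function() {
  list(
    AF = rbind(
      c(57, 140, 85), c(57, 125, 100), c(57, 105, 105), c(57, 90, 95),
      c(57, 82, 75), c(57, 80, 55), c(58, 87, 42)),
    AF_ant = rbind(
      c(62, 138, 80), c(62, 122, 94), c(62, 108, 99), c(62, 96, 99)),
    AF_post = rbind(
      c(58, 86, 102), c(58, 83, 82), c(58, 82, 62), c(59, 85, 46)),
    IFOF = rbind(
      c(52, 150, 70), c(56, 130, 66), c(62, 110, 62), c(58, 85, 64),
      c(54, 60, 66), c(50, 38, 68))
  )
}

# Artefact centerlines; names with a numeric suffix are sub-populations
# generated in equal shares.
phantom_artefact_centerlines <- function() {
  list(
    # follows the AF's longitudinal portion, dips through the axial temporal
    # waypoint, then bends back up to terminate in the parietal lobe
    parietal_ending = list(rbind(
      c(57, 140, 85), c(57, 122, 102), c(57, 95, 100), c(57, 86, 70),
      c(57, 83, 47), c(55, 87, 85), c(52, 91, 130))),
    # short arcs connecting adjacent gyri near an inclusion ROI:
    # variant 1 pierces the AF coronal ROI (parieto-frontal U),
    # variant 2 pierces the AF axial temporal ROI (temporal U)
    u_fiber = list(
      rbind(c(60, 93, 91), c(61, 96, 100), c(61, 103, 100), c(60, 106, 91)),
      rbind(c(53, 79, 62), c(55, 82, 49), c(58, 86, 49), c(60, 89, 62))),
    # passes the IFOF stem then curves back dorsally toward the frontal
    # cortex: variant 1 returns through the extended dorsal exclusion
    # territory; variant 2 arcs higher still and evades even the extended
    # exclusion (the residual contamination seen in final ROI dissections)
    dorsal_loop = list(
      rbind(c(52, 148, 68), c(58, 128, 64), c(62, 110, 62), c(60, 96, 68),
            c(58, 94, 90), c(57, 102, 112), c(56, 118, 114)),
      rbind(c(52, 148, 68), c(57, 126, 64), c(62, 110, 62), c(60, 94, 72),
            c(58, 90, 100), c(57, 92, 128), c(56, 104, 136), c(55, 114, 140))),
    # resembles the AF longitudinal course, then bends inferiorly with a
    # vertical trajectory through the insular territory (misled by medial
    # projection fibers), clipping the axial temporal waypoint on the way
    projection_vertical = list(rbind(
      c(64, 140, 92), c(65, 120, 100), c(67, 104, 97), c(70, 100, 75),
      c(69, 98, 55), c(67, 92, 40), c(66, 88, 34))),
    # crosses the midline plane
    commissural = list(rbind(
      c(68, 112, 78), c(90, 118, 90), c(112, 112, 78)))
  )
}

#' Reference grid of the synthetic phantom space
#'
#' 180 x 216 x 180 voxels at 1 mm isotropic with an identity affine, so world
#' mm equal voxel indices; the sagittal midline sits at x = 90 mm and all
#' bundles occupy the left half.
#'
#' @return A [ref_grid()].
#' @export
phantom_grid <- function() ref_grid(c(180L, 216L, 180L))

#' Bundle and artefact specifications of the default phantom
#'
#' `default_bundle_specs()` returns one spec per association bundle (AF,
#' AF_ant, AF_post, IFOF); `default_artefact_specs()` one per artefact
#' pattern. Counts and dispersion are the tunable knobs; the centerline
#' geometry is the phantom's fixed anatomy.
#'
#' @param n_streamlines Streamlines per bundle (default 500).
#' @param radius Transverse dispersion scale in mm (Rayleigh scale of the
#'   tube offsets; default 2.5).
#' @param step Point spacing along generated streamlines, mm.
#' @param jitter_amp Amplitude bound of the two low-frequency sinusoidal
#'   jitter components, mm.
#' @param end_trim Maximum random arc-length trim at each endpoint, mm.
#' @return A named list of `bundle_spec` / `artefact_spec` objects.
#' @export
default_bundle_specs <- function(n_streamlines = 500, radius = 2.5,
                                 step = 1, jitter_amp = 1, end_trim = 3) {
  cl <- phantom_centerlines()
  out <- lapply(names(cl), function(nm) {
    bundle_spec(nm, cl[[nm]], radius = radius, n_streamlines = n_streamlines,
                step = step, jitter_amp = jitter_amp, end_trim = end_trim)
  })
  stats::setNames(out, names(cl))
}

#' @rdname default_bundle_specs
#' @param counts Named integer vector of streamlines per artefact pattern
#'   (including `background`).
#' @export
default_artefact_specs <- function(counts = c(parietal_ending = 100,
                                              u_fiber = 100,
                                              dorsal_loop = 100,
                                              projection_vertical = 100,
                                              commissural = 100,
                                              background = 1000),
                                   radius = 2, step = 1, jitter_amp = 1,
                                   end_trim = 3) {
  out <- lapply(names(counts), function(nm) {
    artefact_spec(nm, counts[[nm]], radius = radius, step = step,
                  jitter_amp = jitter_amp, end_trim = end_trim)
  })
  stats::setNames(out, names(counts))
}

#' Construct bundle / artefact specifications
#'
#' @param name Bundle name (`AF`, `AF_ant`, `AF_post`, `IFOF`) or, for
#'   artefacts, one of the six pattern names (`parietal_ending`, `u_fiber`,
#'   `dorsal_loop`, `projection_vertical`, `commissural`, `background`).
#' @param centerline Matrix of >= 3 control points (world mm).
#' @param radius Transverse dispersion scale, mm (> 0 unless dispersion is
#'   deliberately disabled with 0).
#' @param n_streamlines Number of streamlines to generate (>= 0).
#' @param step Point spacing along the streamline, mm.
#' @param jitter_amp Sinusoidal jitter amplitude bound, mm.
#' @param end_trim Max random endpoint trim, mm.
#' @return A `bundle_spec` object.
#' @export
bundle_spec <- function(name, centerline, radius = 2.5, n_streamlines = 500,
                        step = 1, jitter_amp = 1, end_trim = 3) {
  centerline <- rbind_points(centerline)
  if (nrow(centerline) < 3) abort("centerline needs >= 3 control points")
  if (radius < 0) abort("radius must be >= 0")
  if (n_streamlines < 0) abort("n_streamlines must be >= 0")
  structure(list(name = name, centerline = centerline, radius = radius,
                 n_streamlines = as.integer(n_streamlines), step = step,
                 jitter_amp = jitter_amp, end_trim = end_trim),
            class = "bundle_spec")
}

#' @rdname bundle_spec
#' @param geometry Optional list of centerline matrices overriding the
#'   built-in pattern geometry (one or more sub-population centerlines).
#' @export
artefact_spec <- function(name, n_streamlines, radius = 2, step = 1,
                          jitter_amp = 1, end_trim = 3, geometry = NULL) {
  known <- c("parietal_ending", "u_fiber", "dorsal_loop",
             "projection_vertical", "commissural", "background")
  if (!name %in% known) {
    abort(sprintf("unknown artefact pattern '%s' (expected one of %s)",
                  name, paste(known, collapse = ", ")))
  }
  if (n_streamlines < 0) abort("n_streamlines must be >= 0")
  structure(list(name = name, n_streamlines = as.integer(n_streamlines),
                 radius = radius, step = step, jitter_amp = jitter_amp,
                 end_trim = end_trim, geometry = geometry),
            class = "artefact_spec")
}

#' Rigid-rotation + anisotropic-scale subject deformation
#'
#' Inter-subject variability is emulated by a small rigid rotation and a
#' per-axis scaling applied to all control points (and to the recipe ROI
#' centers, mirroring per-patient ROI drawing) about the grid center.
#'
#' @param rotation_deg Rotation angle, degrees.
#' @param axis Rotation axis (3-vector, need not be unit length).
#' @param scale Per-axis scale factors (3-vector).
#' @param center Fixed point of the deformation (world mm).
#' @return An object of class `deformation`.
#' @export
deformation <- function(rotation_deg = 0, axis = c(0, 0, 1),
                        scale = c(1, 1, 1), center = c(89.5, 107.5, 89.5)) {
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(rotation_deg = rotation_deg, axis = axis,
                 scale = as.numeric(scale), center = as.numeric(center)),
            class = "deformation")
}

#' @rdname deformation
#' @export
identity_deformation <- function() deformation()

#' @rdname deformation
#' @param max_rotation_deg,max_scale_dev Bounds for the random draw
#'   (rotation magnitude in degrees; scale in `1 +- max_scale_dev`).
#' @param seed Integer seed.
#' @export
random_deformation <- function(max_rotation_deg = 4, max_scale_dev = 0.04,
                               seed = NULL, center = c(89.5, 107.5, 89.5)) {
  if (max_rotation_deg > 10 || max_scale_dev > 0.10) {
    abort("deformation limits exceed the supported bounds (10 deg, 10% scale)")
  }
  with_local_seed(seed, {
    ax <- stats::rnorm(3)
    deformation(rotation_deg = stats::runif(1, 0, max_rotation_deg),
                axis = ax,
                scale = stats::runif(3, 1 - max_scale_dev, 1 + max_scale_dev),
                center = center)
  })
}

rotation_matrix <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  u <- axis
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a subject deformation to world-mm points
#'
#' Scaling is applied first, then the rotation, both about the deformation
#' center.
#'
#' @param points n x 3 matrix of world-mm points.
#' @param def A [deformation()] (or `NULL` for identity).
#' @return The deformed n x 3 matrix.
#' @export
apply_deformation <- function(points, def) {
  if (is.null(def)) return(rbind_points(points))
  points <- rbind_points(points)
  ctr <- matrix(def$center, nrow(points), 3, byrow = TRUE)
  p <- (points - ctr) %*% diag(def$scale)
  p <- p %*% t(rotation_matrix(def$axis, def$rotation_deg))
  p + ctr
}

# Sample a smooth curve through control points at ~step mm spacing
# (natural cubic spline per coordinate over chord-length parameter).
sample_centerline <- function(control, step = 1) {
  cs <- cumulative_arclength(control)
  total <- cs[length(cs)]
  n_out <- max(2L, ceiling(total / step) + 1L)
  u <- seq(0, total, length.out = n_out)
  cbind(
    spline(cs, control[, 1], xout = u, method = "natural")$y,
    spline(cs, control[, 2], xout = u, method = "natural")$y,
    spline(cs, control[, 3], xout = u, method = "natural")$y
  )
}

# Orthonormal frame perpendicular to the local tangent at every point of a
# sampled centerline; the helper vector is fixed per curve so the frame does
# not flip along the course.
centerline_frames <- function(path) {
  n <- nrow(path)
  tang <- matrix(0, n, 3)
  tang[1, ] <- path[2, ] - path[1, ]
  tang[n, ] <- path[n, ] - path[n - 1, ]
  if (n > 2) tang[2:(n - 1), ] <- path[3:n, , drop = FALSE] - path[1:(n - 2), , drop = FALSE]
  tang <- tang / sqrt(rowSums(tang^2))
  mean_t <- abs(colMeans(tang))
  h <- diag(3)[, which.min(mean_t)]
  n1 <- cbind(tang[, 2] * h[3] - tang[, 3] * h[2],
              tang[, 3] * h[1] - tang[, 1] * h[3],
              tang[, 1] * h[2] - tang[, 2] * h[1])
  n1 <- n1 / sqrt(rowSums(n1^2))
  n2 <- cbind(tang[, 2] * n1[, 3] - tang[, 3] * n1[, 2],
              tang[, 3] * n1[, 1] - tang[, 1] * n1[, 3],
              tang[, 1] * n1[, 2] - tang[, 2] * n1[, 1])
  list(n1 = n1, n2 = n2)
}

# One tube streamline: random constant transverse offset (Rayleigh-scaled)
# plus two low-frequency sinusoidal jitter waves in the normal plane, with
# random endpoint trimming. RNG draws: must stay a fixed count per call so
# the per-streamline stream is reproducible.
tube_streamline <- function(path, frames, cs, radius, jitter_amp, end_trim) {
  total <- cs[length(cs)]
  r <- radius * sqrt(-2 * log(stats::runif(1)))
  phi <- stats::runif(1, 0, 2 * pi)
  a <- stats::runif(2, 0, jitter_amp)
  f <- stats::runif(2, 0.5, 1.5)
  ph <- stats::runif(2, 0, 2 * pi)
  psi <- stats::runif(2, 0, 2 * pi)
  trim <- stats::runif(2, 0, end_trim)
  keep <- which(cs >= trim[1] & cs <= total - trim[2])
  if (length(keep) < 2) keep <- c(1L, nrow(path))
  u <- cs[keep] / total
  c1 <- r * cos(phi) + a[1] * sin(2 * pi * f[1] * u + ph[1]) * cos(psi[1]) +
    a[2] * sin(2 * pi * f[2] * u + ph[2]) * cos(psi[2])
  c2 <- r * sin(phi) + a[1] * sin(2 * pi * f[1] * u + ph[1]) * sin(psi[1]) +
    a[2] * sin(2 * pi * f[2] * u + ph[2]) * sin(psi[2])
  path[keep, , drop = FALSE] + c1 * frames$n1[keep, , drop = FALSE] +
    c2 * frames$n2[keep, , drop = FALSE]
}

generate_tube_set <- function(control, n, radius, step, jitter_amp, end_trim,
                              deformation = NULL) {
  if (n == 0L) return(list())
  ctrl <- apply_deformation(control, deformation)
  path <- sample_centerline(ctrl, step)
  frames <- centerline_frames(path)
  cs <- cumulative_arclength(path)
  lapply(seq_len(n), function(i) {
    tube_streamline(path, frames, cs, radius, jitter_amp, end_trim)
  })
}

#' Generate one labeled synthetic bundle
#'
#' Streamlines are smooth perturbations of the (deformed) centerline: a
#' constant transverse offset with Rayleigh-distributed magnitude at scale
#' `radius`, two low-frequency sinusoidal jitter waves, and random endpoint
#' trimming. Deterministic given `seed`.
#'
#' @param spec A [bundle_spec()].
#' @param deformation A [deformation()] or `NULL`.
#' @param seed Integer seed.
#' @return A list with elements `streamlines` (list of matrices) and
#'   `labels` (character vector, all equal to `spec$name`).
#' @export
generate_bundle <- function(spec, deformation = NULL, seed = NULL) {
  stopifnot(inherits(spec, "bundle_spec"))
  sl <- with_local_seed(seed, {
    generate_tube_set(spec$centerline, spec$n_streamlines, spec$radius,
                      spec$step, spec$jitter_amp, spec$end_trim, deformation)
  })
  list(streamlines = sl, labels = rep(spec$name, length(sl)))
}

# background clutter: smooth random polylines in the left half of the grid.
# Natural-spline interpolation can overshoot the control hull, so candidates
# leaving a safe margin box are rejected and redrawn (deterministic under
# the caller's seeded RNG).
generate_background <- function(n, grid, radius, step, jitter_amp) {
  if (n == 0L) return(list())
  lo <- c(15, 20, 15)
  hi <- c(80, pmin(grid$dims[2] - 26, 190), pmin(grid$dims[3] - 26, 154))
  safe_lo <- 2
  safe_hi <- grid$dims - 3
  lapply(seq_len(n), function(i) {
    for (attempt in 1:25) {
      start <- stats::runif(3, lo, hi)
      steps <- matrix(stats::rnorm(9, sd = 22), 3, 3)
      ctrl <- apply(rbind(start, steps), 2, cumsum)
      ctrl <- pmin(pmax(ctrl, matrix(lo, 4, 3, byrow = TRUE)),
                   matrix(hi, 4, 3, byrow = TRUE))
      # collapse of consecutive control points is possible after clamping;
      # nudge until distinct
      for (j in 2:4) {
        if (sum((ctrl[j, ] - ctrl[j - 1, ])^2) < 1) {
          ctrl[j, ] <- ctrl[j - 1, ] + stats::rnorm(3, sd = 3)
        }
      }
      path <- sample_centerline(ctrl, step)
      frames <- centerline_frames(path)
      cs <- cumulative_arclength(path)
      s <- tube_streamline(path, frames, cs, radius, jitter_amp, 0)
      inside <- all(sweep(s, 2, safe_lo, ">=")) && all(sweep(s, 2, safe_hi, "<="))
      if (inside) return(s)
    }
    # fall back to a short straight filler deep inside the grid
    straight <- rbind(c(40, 60, 60), c(45, 80, 70))
    sample_centerline(rbind(straight[1, ], colMeans(straight), straight[2, ]),
                      step)
  })
}

#' Generate labeled artefact streamline populations
#'
#' Each pattern has a characteristic built-in geometry (see the module
#' overview); sub-populations (e.g. the two U-fiber variants) are generated
#' in equal shares. Deterministic given `seed`.
#'
#' @param specs A list of [artefact_spec()]s.
#' @param deformation A [deformation()] or `NULL`.
#' @param seed Integer seed.
#' @param grid A [ref_grid()] (needed for the `background` pattern).
#' @return A list with elements `streamlines` and `labels`.
#' @export
generate_artefacts <- function(specs, deformation = NULL, seed = NULL,
                               grid = phantom_grid()) {
  if (inherits(specs, "artefact_spec")) specs <- list(specs)
  atlas <- phantom_artefact_centerlines()
  out_sl <- list()
  out_lb <- character()
  with_local_seed(seed, {
    for (spec in specs) {
      stopifnot(inherits(spec, "artefact_spec"))
      if (spec$n_streamlines == 0L) next
      if (spec$name == "background") {
        sl <- generate_background(spec$n_streamlines, grid, spec$radius,
                                  spec$step, spec$jitter_amp)
      } else {
        geoms <- spec$geometry %||% atlas[[spec$name]]
        shares <- diff(round(seq(0, spec$n_streamlines, length.out = length(geoms) + 1)))
        sl <- list()
        for (g in seq_along(geoms)) {
          sl <- c(sl, generate_tube_set(geoms[[g]], shares[g], spec$radius,
                                        spec$step, spec$jitter_amp,
                                        spec$end_trim, deformation))
        }
      }
      out_sl <- c(out_sl, sl)
      out_lb <- c(out_lb, rep(spec$name, length(sl)))
    }
  })
  list(streamlines = out_sl, labels = out_lb)
}

#' Subject specification for a phantom cohort
#'
#' @param subject_id Integer id, unique within a cohort.
#' @param seed Integer seed driving every random draw for the subject.
#' @param deformation A [deformation()].
#' @return An object of class `subject_spec`.
#' @export
subject_spec <- function(subject_id, seed, deformation = identity_deformation()) {
  structure(list(subject_id = as.integer(subject_id), seed = as.integer(seed),
                 deformation = deformation),
            class = "subject_spec")
}

#' Generate one labeled phantom subject
#'
#' Unions the bundle and artefact populations under the subject's
#' deformation; every streamline is labeled and every point is checked to
#' lie inside the grid.
#'
#' @param bundles List of [bundle_spec()]s.
#' @param artefacts List of [artefact_spec()]s.
#' @param subj A [subject_spec()].
#' @param grid A [ref_grid()].
#' @return A [tractogram()] with complete labels. The subject's deformed
#'   bundle centerlines are attached as `attr(, "templates")` (used as
#'   segmentation templates) and the deformation as `attr(, "deformation")`.
#' @export
generate_subject <- function(bundles = default_bundle_specs(),
                             artefacts = default_artefact_specs(),
                             subj = subject_spec(1, 1),
                             grid = phantom_grid()) {
  def <- subj$deformation
  sl <- list()
  lb <- character()
  for (j in seq_along(bundles)) {
    b <- generate_bundle(bundles[[j]], def, seed = subj$seed + 1000L * j)
    sl <- c(sl, b$streamlines)
    lb <- c(lb, b$labels)
  }
  a <- generate_artefacts(artefacts, def, seed = subj$seed + 777L, grid = grid)
  sl <- c(sl, a$streamlines)
  lb <- c(lb, a$labels)
  if (length(sl)) {
    pts <- do.call(rbind, sl)
    idx <- voxel_index(grid, pts)
    if (!all(in_grid(grid, idx))) {
      abort("generated points fall outside the grid (grid too small)")
    }
  }
  t <- tractogram(sl, grid, labels = lb, validate = FALSE)
  templates <- lapply(bundles, function(b) {
    sample_centerline(apply_deformation(b$centerline, def), b$step)
  })
  names(templates) <- vapply(bundles, function(b) b$name, character(1))
  attr(t, "templates") <- templates
  attr(t, "deformation") <- def
  attr(t, "subject_id") <- subj$subject_id
  t
}

#' Deformed bundle centerlines of a phantom subject
#'
#' @param t A tractogram produced by [generate_subject()].
#' @return Named list of centerline matrices.
#' @export
phantom_templates <- function(t) {
  tm <- attr(t, "templates")
  if (is.null(tm)) abort("tractogram carries no phantom templates")
  tm
}

#' Generate a phantom cohort
#'
#' Each subject gets a distinct seed (`master_seed + subject_id`) and a
#' random deformation; the whole cohort is deterministic given
#' `master_seed`.
#'
#' @param n_subjects Number of subjects (>= 2; paired statistics are
#'   undefined for fewer). Default 25.
#' @param master_seed Master seed.
#' @param bundles,artefacts,grid As in [generate_subject()].
#' @param max_rotation_deg,max_scale_dev Deformation limits.
#' @return An object of class `phantom_cohort`: a list of subjects, each a
#'   list with `tract` (labeled tractogram) and `spec` (the subject_spec).
#' @export
generate_cohort <- function(n_subjects = 25, master_seed = 42,
                            bundles = default_bundle_specs(),
                            artefacts = default_artefact_specs(),
                            grid = phantom_grid(),
                            max_rotation_deg = 4, max_scale_dev = 0.04) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 2L) {
    abort("`n_subjects` must be >= 2 (paired statistics are undefined otherwise)")
  }
  subjects <- lapply(seq_len(n_subjects), function(i) {
    seed <- as.integer(master_seed) + i
    def <- random_deformation(max_rotation_deg, max_scale_dev, seed = seed * 7L,
                              center = (grid$dims - 1) / 2)
    sp <- subject_spec(i, seed, def)
    list(tract = generate_subject(bundles, artefacts, sp, grid), spec = sp)
  })
  structure(subjects, class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("<phantom_cohort> ", length(x), " subjects, ",
      n_streamlines(x[[1]]$tract), " streamlines each\n", sep = "")
  invisible(x)
}
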