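# Synthetic phantom generator: bundles, artefact populations, subjects,
# cohorts, determinism, and the designed confound structure.

test_that("zero-dispersion bundles collapse onto the centerline", {
  spec <- bundle_spec("AF", phantom_centerline_fixture(), radius = 0,
                      n_streamlines = 3, jitter_amp = 0, end_trim = 0)
  b <- generate_bundle(spec, seed = 1)
  expect_length(b$streamlines, 3L)
  # all identical, and passing through every control point
  expect_equal(b$streamlines[[1]], b$streamlines[[2]], tolerance = 1e-9)
  ctrl <- spec$centerline
  s <- b$streamlines[[1]]
  # endpoints are the centerline endpoints exactly; interior control points
  # lie on the sampled polyline (up to the 1 mm sampling chord)
  expect_equal(s[1, ], ctrl[1, ], tolerance = 1e-9)
  expect_equal(s[nrow(s), ], ctrl[nrow(ctrl), ], tolerance = 1e-9)
  dense <- dense_walk(s, 0.01)
  for (i in seq_len(nrow(ctrl))) {
    expect_lt(min(sqrt(rowSums(sweep(dense, 2, ctrl[i, ])^2))), 0.05)
  }
})

test_that("generation is deterministic given the seed and spec", {
  spec <- default_bundle_specs(n_streamlines = 5)$AF
  b1 <- generate_bundle(spec, seed = 9)
  b2 <- generate_bundle(spec, seed = 9)
  expect_identical(b1$streamlines, b2$streamlines)
  b3 <- generate_bundle(spec, seed = 10)
  expect_false(identical(b1$streamlines, b3$streamlines))
  empty <- generate_bundle(bundle_spec("AF", spec$centerline, n_streamlines = 0),
                           seed = 1)
  expect_length(empty$streamlines, 0L)
})

test_that("artefact populations honor their constructed geometry", {
  specs <- small_artefact_specs(n = 30, background = 30)
  a <- generate_artefacts(specs, seed = 3)
  lab <- a$labels
  # commissural streamlines have points strictly on both sides of the midline
  mid <- slice_filter("x", 90)
  for (s in a$streamlines[lab == "commissural"]) {
    expect_true(streamline_crosses_slice(s, mid))
  }
  # u-fibers are short (< 40 mm)
  for (s in a$streamlines[lab == "u_fiber"]) {
    expect_lt(streamline_arclength(s), 40)
  }
  # parietal-ending streamlines cross BOTH AF waypoint ROIs (that is what
  # makes them leak into the AF recipe) yet terminate dorsally, not in the
  # temporal lobe
  rec <- default_recipes()
  af_boxes <- Filter(function(tm) inherits(tm, "roi_term") &&
                       tm$logic == "any_part", rec$AF$terms)
  g <- phantom_grid()
  for (s in a$streamlines[lab == "parietal_ending"]) {
    for (box in af_boxes) expect_true(streamline_in_roi(s, box, g))
    expect_gt(s[1, 3], 75)          # frontal origin, superior
    expect_gt(s[nrow(s), 3], 75)    # parietal termination, superior
  }
  expect_error(artefact_spec("wiggly", 5), "unknown artefact pattern")
})

test_that("subjects assemble bundles + artefacts with complete labels", {
  tr <- generate_subject(small_bundle_specs(50), small_artefact_specs(10, 40),
                         subject_spec(1, 5))
  expect_equal(n_streamlines(tr), 4L * 50L + 5L * 10L + 40L)
  lab <- tract_labels(tr)
  expect_false(any(is.na(lab$label)))
  expect_identical(sort(unique(lab$label)),
                   sort(c("AF", "AF_ant", "AF_post", "IFOF", "parietal_ending",
                          "u_fiber", "dorsal_loop", "projection_vertical",
                          "commissural", "background")))
  # all points inside the grid
  pts <- do.call(rbind, tr$streamlines)
  idx <- voxel_index(tr$grid, pts)
  expect_true(all(idx >= 0) && all(idx < matrix(tr$grid$dims, nrow(idx), 3, TRUE)))
  # no bundle-labeled streamline crosses the midline
  mid <- slice_filter("x", 90)
  bundle_ids <- which(lab$label %in% c("AF", "AF_ant", "AF_post", "IFOF"))
  expect_false(any(vapply(tr$streamlines[bundle_ids],
                          streamline_crosses_slice, TRUE, f = mid)))
})

test_that("a rigid rotation displaces endpoints per the matrix oracle", {
  ctrl <- phantom_centerline_fixture()
  def <- deformation(rotation_deg = 5, axis = c(0, 0, 1), center = c(50, 50, 50))
  spec <- bundle_spec("AF", ctrl, radius = 0, n_streamlines = 1,
                      jitter_amp = 0, end_trim = 0)
  b <- generate_bundle(spec, deformation = def, seed = 2)
  s <- b$streamlines[[1]]
  th <- 5 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  for (row in c(1L, nrow(ctrl))) {
    manual <- as.vector(R %*% (ctrl[row, ] - c(50, 50, 50))) + c(50, 50, 50)
    endpoint <- if (row == 1L) s[1, ] else s[nrow(s), ]
    expect_equal(endpoint, manual, tolerance = 1e-9)
  }
})

test_that("cohorts are sized, seeded, and reproducible", {
  co1 <- generate_cohort(3, master_seed = 21, bundles = small_bundle_specs(10),
                         artefacts = small_artefact_specs(5, 10))
  co2 <- generate_cohort(3, master_seed = 21, bundles = small_bundle_specs(10),
                         artefacts = small_artefact_specs(5, 10))
  expect_length(co1, 3L)
  expect_identical(lapply(co1, function(s) s$tract$streamlines),
                   lapply(co2, function(s) s$tract$streamlines))
  # subjects differ from one another
  expect_false(identical(co1[[1]]$tract$streamlines,
                         co1[[2]]$tract$streamlines))
  expect_identical(vapply(co1, function(s) s$spec$subject_id, 0L), 1:3)
  expect_error(generate_cohort(1, master_seed = 1), ">= 2")
})

test_that("each artefact pattern leaks into its target default recipe", {
  def <- random_deformation(seed = 70)
  tr <- generate_subject(subj = subject_spec(1, 10, def))
  lab <- tract_labels(tr)$label
  rec <- default_recipes(tr$grid, deformation = def)
  ids <- apply_recipes(tr, rec)
  leak <- function(bundle, pattern) sum(lab[ids[[bundle]]] == pattern)
  kept <- function(bundle) sum(lab[ids[[bundle]]] == bundle)
  # the designed confounds survive the inclusion filters
  expect_gte(leak("AF", "parietal_ending"), 80)
  expect_gte(leak("AF_ant", "u_fiber"), 35)
  expect_gte(leak("AF_post", "u_fiber"), 35)
  expect_gte(leak("IFOF", "dorsal_loop"), 25)
  # and nearly all true members are retained (the recipes are supersets of
  # the ground truth up to extreme dispersion tails)
  for (b in c("AF", "AF_ant", "AF_post", "IFOF")) {
    expect_gte(kept(b), 497)
  }
})
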