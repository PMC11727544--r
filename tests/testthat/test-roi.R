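# ROI filter semantics, slice filters, recipe conjunction, and the default
# bundle recipes on phantom subjects.

test_that("any_part / no_part semantics on full and empty masks", {
  g <- ref_grid(c(10L, 10L, 10L))
  s <- straight_streamline(c(1, 1, 1), c(8, 8, 8), 5)
  full <- binary_mask(g, array(TRUE, g$dims))
  empty <- binary_mask(g, array(FALSE, g$dims))
  expect_true(streamline_in_roi(s, roi_mask(full, "any_part"), g))
  expect_false(streamline_in_roi(s, roi_mask(full, "no_part"), g))
  suppressWarnings({
    expect_false(streamline_in_roi(s, roi_mask(empty, "any_part"), g))
    expect_true(streamline_in_roi(s, roi_mask(empty, "no_part"), g))
  })
})

test_that("segment supersampling catches regions pierced between vertices", {
  g <- ref_grid(c(20L, 20L, 20L))
  # segment passes straight through voxel (10,10,10); vertices far outside
  s <- straight_streamline(c(2, 10, 10), c(18, 10, 10))
  arr <- array(FALSE, g$dims)
  arr[11, 11, 11] <- TRUE
  expect_true(streamline_in_roi(s, roi_mask(binary_mask(g, arr), "any_part"), g))
  thin <- roi_box(c(9.8, 10.2), c(8, 12), c(8, 12), "any_part")
  expect_true(streamline_in_roi(s, thin, g))
  # dense 0.01 mm oracle agreement on random segment/box pairs
  set.seed(12)
  for (i in 1:40) {
    s2 <- straight_streamline(runif(3, 0, 20), runif(3, 0, 20))
    ctr <- runif(3, 4, 16)
    box <- roi_box(ctr[1] + c(-1, 1) * runif(1, 0.2, 3),
                   ctr[2] + c(-1, 1) * runif(1, 0.2, 3),
                   ctr[3] + c(-1, 1) * runif(1, 0.2, 3), "any_part")
    dense <- dense_walk(s2, 0.01)
    oracle <- any(dense[, 1] >= box$lim[1, 1] & dense[, 1] <= box$lim[1, 2] &
                    dense[, 2] >= box$lim[2, 1] & dense[, 2] <= box$lim[2, 2] &
                    dense[, 3] >= box$lim[3, 1] & dense[, 3] <= box$lim[3, 2])
    expect_identical(streamline_in_roi(s2, box, g, spacing = 0.01), oracle)
  }
})

test_that("slice crossing uses strict sides", {
  f <- slice_filter("x", 5)
  expect_false(streamline_crosses_slice(straight_streamline(c(1, 0, 0), c(4, 5, 5)), f))
  expect_true(streamline_crosses_slice(straight_streamline(c(1, 0, 0), c(9, 5, 5)), f))
  # touching the plane exactly without crossing
  touch <- rbind(c(3, 0, 0), c(5, 2, 0), c(3, 4, 0))
  expect_false(streamline_crosses_slice(touch, f))
})

test_that("recipes are conjunctions matching per-term brute force", {
  g <- ref_grid(c(40L, 40L, 40L))
  coronal <- roi_box(c(5, 35), c(18, 22), c(20, 35), "any_part")
  axial <- roi_box(c(5, 35), c(5, 15), c(8, 12), "any_part")
  mid <- slice_filter("x", 36)
  rec <- bundle_recipe("toy", list(coronal, axial, mid))
  s_both <- rbind(c(20, 30, 30), c(20, 20, 28), c(20, 10, 10))   # both ROIs
  s_coronal <- rbind(c(20, 30, 30), c(20, 20, 28), c(20, 16, 25)) # coronal only
  s_cross <- rbind(c(20, 30, 30), c(20, 20, 28), c(39, 10, 10))   # both + crosses
  t <- tractogram(list(s_both, s_coronal, s_cross), g)
  expect_identical(apply_recipe(t, rec), 1L)
  # naive per-streamline, per-term evaluation agrees
  naive <- which(vapply(t$streamlines, function(s) {
    streamline_in_roi(s, coronal, g) && streamline_in_roi(s, axial, g) &&
      !streamline_crosses_slice(s, mid)
  }, TRUE))
  expect_identical(apply_recipe(t, rec), naive)
  # total inclusion keeps all non-crossers; total exclusion empties the set
  whole <- roi_box(c(0, 39), c(0, 39), c(0, 39), "any_part")
  expect_identical(apply_recipe(t, bundle_recipe("all", list(whole, mid))),
                   c(1L, 2L))
  kill <- roi_box(c(0, 39), c(0, 39), c(0, 39), "no_part")
  expect_identical(apply_recipe(t, bundle_recipe("none", list(whole, kill))),
                   integer(0))
  expect_error(bundle_recipe("bad", list(kill)), "inclusion")
})

test_that("adding exclusion terms never enlarges the selection", {
  set.seed(33)
  g <- ref_grid(c(40L, 40L, 40L))
  for (rep in 1:10) {
    t <- random_tractogram(20, g)
    base <- bundle_recipe("r", list(roi_box(c(0, 39), c(0, 39), c(0, 39),
                                            "any_part")))
    ids <- apply_recipe(t, base)
    grown <- base
    for (extra in 1:4) {
      ctr <- runif(3, 5, 35)
      excl <- roi_box(ctr[1] + c(-4, 4), ctr[2] + c(-4, 4), ctr[3] + c(-4, 4),
                      "no_part")
      grown$terms <- c(grown$terms, list(excl))
      ids_new <- apply_recipe(t, grown)
      expect_true(all(ids_new %in% ids))
      ids <- ids_new
    }
  }
})

test_that("vectorized recipe evaluation equals the naive path on random data", {
  set.seed(91)
  g <- ref_grid(c(40L, 40L, 40L))
  t <- random_tractogram(200, g)
  terms <- list(
    roi_box(c(5, 30), c(5, 30), c(5, 30), "any_part"),
    roi_box(c(18, 26), c(2, 38), c(10, 20), "no_part"),
    slice_filter("y", 20)
  )
  rec <- bundle_recipe("r", terms)
  naive <- which(vapply(t$streamlines, function(s) {
    streamline_in_roi(s, terms[[1]], g) && streamline_in_roi(s, terms[[2]], g) &&
      !streamline_crosses_slice(s, terms[[3]])
  }, TRUE))
  expect_identical(apply_recipe(t, rec), naive)
})

test_that("default recipes recover exactly the labels on artefact-free phantoms", {
  specs <- small_bundle_specs(80)
  tr <- generate_subject(specs, artefacts = list(), subj = subject_spec(1, 4))
  lab <- tract_labels(tr)$label
  rec <- default_recipes(tr$grid)
  ids <- apply_recipes(tr, rec)
  for (b in names(rec)) {
    expect_identical(ids[[b]], which(lab == b))
  }
})

test_that("the posterior-segment recipe admits no frontal terminations", {
  def <- random_deformation(seed = 14)
  tr <- generate_subject(small_bundle_specs(80), small_artefact_specs(20, 50),
                         subj = subject_spec(1, 6, def))
  rec <- default_recipes(tr$grid, deformation = def)
  ids <- apply_recipes(tr, rec)$AF_post
  plane_y <- Filter(function(tm) inherits(tm, "roi_term") &&
                      tm$logic == "no_part", rec$AF_post$terms)[[1]]$lim[2, 1]
  expect_gt(length(ids), 0)
  for (s in tr$streamlines[ids]) {
    expect_lt(max(s[, 2]), plane_y)
  }
})

test_that("extending the IFOF exclusions strictly shrinks the selection", {
  specs <- small_bundle_specs(60)
  arte <- list(artefact_spec("dorsal_loop", 40))
  tr <- generate_subject(specs, arte, subj = subject_spec(1, 8))
  lab <- tract_labels(tr)$label
  plain <- apply_recipes(tr, default_recipes(tr$grid, ifof_extended = FALSE))$IFOF
  ext <- apply_recipes(tr, default_recipes(tr$grid, ifof_extended = TRUE))$IFOF
  expect_true(all(ext %in% plain))
  expect_lt(length(ext), length(plain))
  # the removed streamlines are dorsal loops, not true IFOF members
  removed <- setdiff(plain, ext)
  expect_true(all(lab[removed] == "dorsal_loop"))
})

test_that("the insula exclusion removes vertical projection-like artefacts", {
  specs <- small_bundle_specs(60)
  arte <- list(artefact_spec("projection_vertical", 40))
  tr <- generate_subject(specs, arte, subj = subject_spec(1, 9))
  lab <- tract_labels(tr)$label
  with_excl <- apply_recipes(tr, default_recipes(tr$grid))$AF
  without <- apply_recipes(tr, default_recipes(tr$grid, insula_exclusion = FALSE))$AF
  expect_gte(sum(lab[without] == "projection_vertical"), 30)
  expect_lte(sum(lab[with_excl] == "projection_vertical"), 3)
  # true AF members are untouched by the insula block
  expect_identical(intersect(with_excl, which(lab == "AF")),
                   intersect(without, which(lab == "AF")))
})
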