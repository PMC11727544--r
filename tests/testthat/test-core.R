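# Streamline / tractogram data model, geometric primitives, whole-tractogram
# resampling, and the world <-> voxel mapping.

test_that("streamline and grid validation rejects degenerate inputs", {
  g <- ref_grid(c(10, 10, 10))
  expect_error(tractogram(list(matrix(c(0, 0, 0), 1, 3)), g), "2 points")
  expect_error(tractogram(list(rbind(c(0, 0, 0), c(0, 0, NA))), g), "finite")
  expect_error(tractogram(list(rbind(c(1, 1, 1), c(1, 1, 1))), g), "distinct")
  expect_error(ref_grid(c(10, 10)), "3 positive integers")
  expect_error(ref_grid(c(10, 10, 10), matrix(0, 4, 4)), "invertible")
  expect_error(streamline_arclength(matrix(c(0, 0, 0), 1, 3)), "2 points")
})

test_that("arc length equals the brute-force segment sum", {
  expect_equal(streamline_arclength(straight_streamline(c(0, 0, 0), c(0, 0, 10))), 10)
  square <- rbind(c(0, 0, 0), c(5, 0, 0), c(5, 5, 0), c(0, 5, 0), c(0, 0, 0))
  expect_equal(streamline_arclength(square), 20)
  set.seed(41)
  s <- random_polyline(50)
  brute <- 0
  for (i in seq_len(nrow(s) - 1)) brute <- brute + sqrt(sum((s[i + 1, ] - s[i, ])^2))
  expect_equal(streamline_arclength(s), brute, tolerance = 1e-12)
})

test_that("point resampling is equidistant in arc length", {
  s <- straight_streamline(c(0, 0, 0), c(0, 0, 10))
  r <- resample_streamline_points(s, 3)
  expect_equal(r[2, ], c(0, 0, 5))
  expect_identical(r[1, ], s[1, ])
  expect_identical(r[3, ], s[2, ])
  # idempotence on an already-equidistant polyline
  r5 <- resample_streamline_points(straight_streamline(c(0, 0, 0), c(0, 0, 8), 5), 5)
  expect_equal(r5, resample_streamline_points(r5, 5), tolerance = 1e-6)
  # right-angle polyline against a dense 0.001 mm arc-length walk
  elbow <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0))
  r <- resample_streamline_points(elbow, 5)
  walk <- dense_walk(elbow, 0.001)
  wl <- c(0, cumsum(sqrt(rowSums(diff(walk)^2))))
  for (j in 1:5) {
    target <- (j - 1) * 5
    expect_lt(max(abs(r[j, ] - walk[which.min(abs(wl - target)), ])), 0.01)
  }
  expect_error(resample_streamline_points(s, 1), ">= 2")
})

test_that("count resampling draws exact, deterministic, uniform subsets", {
  g <- ref_grid(c(50, 50, 50))
  sl <- lapply(1:100, function(i) straight_streamline(c(i %% 40, 0, 0), c(i %% 40, 10, 0)))
  t <- tractogram(sl, g, labels = paste0("s", 1:100), validate = FALSE)
  expect_identical(resample_tractogram_count(t, 100, seed = 1)$streamlines,
                   t$streamlines)
  a <- resample_tractogram_count(t, 10, seed = 7)
  b <- resample_tractogram_count(t, 10, seed = 7)
  expect_identical(a$streamlines, b$streamlines)
  expect_identical(a$labels, b$labels)
  expect_equal(n_streamlines(a), 10L)
  # drawn from the original set, no duplicates
  keys <- vapply(a$streamlines, function(s) paste(s[1, ], collapse = ","), "")
  expect_length(unique(a$labels), 10L)
  expect_true(all(a$labels %in% t$labels))
  expect_error(resample_tractogram_count(t, 200, seed = 1), "allow_duplicates")
  up <- resample_tractogram_count(t, 150, seed = 1, allow_duplicates = TRUE)
  expect_equal(n_streamlines(up), 150L)
})

test_that("downsampling is measure-preserving in expectation", {
  g <- ref_grid(c(50, 50, 50))
  sl <- lapply(1:100, function(i) straight_streamline(c(i %% 40, 0, 0), c(i %% 40, 10, 0)))
  t <- tractogram(sl, g, labels = as.character(1:100), validate = FALSE)
  hits <- integer(100)
  for (rep in 1:1000) {
    ids <- as.integer(resample_tractogram_count(t, 10, seed = 5000 + rep)$labels)
    hits[ids] <- hits[ids] + 1L
  }
  freq <- hits / 1000
  # each draw keeps exactly 10 of 100 ids, so the mean inclusion frequency
  # is 0.1 by construction; uniformity bounds every id's frequency (100
  # simultaneous binomials, hence a 4-sigma band)
  expect_equal(mean(freq), 0.1)
  sigma <- sqrt(0.1 * 0.9 / 1000)
  expect_true(all(abs(freq - 0.1) <= 4 * sigma))
})

test_that("world <-> voxel mapping is a bijection on voxel centers", {
  aff <- rbind(c(2, 0, 0, -7), c(0, 1.5, 0, 3), c(0, 0, 1, -2), c(0, 0, 0, 1))
  for (g in list(ref_grid(c(10, 10, 10)), ref_grid(c(10, 10, 10), aff))) {
    idx <- as.matrix(expand.grid(0:9, 0:9, 0:9))
    colnames(idx) <- NULL
    world <- voxel_to_world(g, idx)
    back <- voxel_index(g, world)
    expect_identical(back, matrix(as.integer(idx), ncol = 3))
  }
  # half-open convention: a point exactly on the -0.5 face belongs to the
  # voxel, the +0.5 face to the next one
  g <- ref_grid(c(10, 10, 10))
  expect_identical(as.vector(voxel_index(g, c(1.5, 0, 0))), c(2L, 0L, 0L))
  expect_identical(as.vector(voxel_index(g, c(1.49999, 0, 0))), c(1L, 0L, 0L))
})

test_that("tractogram tibble bridge and label handling are consistent", {
  g <- ref_grid(c(10, 10, 10))
  t <- tractogram(list(straight_streamline(c(0, 0, 0), c(0, 0, 5), 3),
                       straight_streamline(c(1, 1, 1), c(1, 4, 1))),
                  g, labels = data.frame(id = 2L, label = "AF"))
  tb <- tibble::as_tibble(t)
  expect_equal(nrow(tb), 5L)
  expect_identical(tb$label, c(NA, NA, NA, "AF", "AF"))
  expect_identical(tract_labels(t)$label, c(NA, "AF"))
  sub <- subset_tractogram(t, 2L)
  expect_identical(sub$labels, "AF")
  expect_error(tractogram(list(), g, labels = data.frame(id = 1, label = "x")),
               "within 1..n")
})
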