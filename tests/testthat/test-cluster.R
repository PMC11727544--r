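# MDF metric, dissimilarity-embedding clustering with medoid prototypes,
# selection operations, and the template-guided segmentation policy.

test_that("MDF satisfies the worked examples and matches the pure-R oracle", {
  a <- straight_streamline(c(0, 0, 0), c(0, 0, 50), 10)
  expect_equal(mdf_distance(a, a), 0)
  expect_equal(mdf_distance(a, a[10:1, ]), 0)
  b <- straight_streamline(c(3, 0, 0), c(3, 0, 50), 10)
  expect_equal(mdf_distance(a, b), 3)
  set.seed(8)
  for (i in 1:25) {
    p <- random_polyline(sample(4:15, 1))
    q <- random_polyline(sample(4:15, 1))
    expect_equal(mdf_distance(p, q), mdf_oracle(p, q), tolerance = 1e-9)
  }
})

test_that("MDF is symmetric, flip-invariant, and non-negative", {
  set.seed(17)
  for (i in 1:200) {
    p <- random_polyline(6)
    q <- random_polyline(9)
    d <- mdf_distance(p, q)
    expect_gte(d, 0)
    expect_equal(d, mdf_distance(q, p), tolerance = 1e-12)
    expect_equal(d, mdf_distance(p, q[nrow(q):1, ]), tolerance = 1e-9)
  }
})

two_bundle_tract <- function(n_per = 20, sep = 100, sd = 2, seed = 5) {
  set.seed(seed)
  mk <- function(x0) {
    lapply(seq_len(n_per), function(i) {
      off <- rnorm(2, sd = sd)
      straight_streamline(c(x0 + off[1], 10, 10 + off[2]),
                          c(x0 + off[1], 90, 10 + off[2]), 12)
    })
  }
  tractogram(c(mk(20), mk(20 + sep)), ref_grid(c(200L, 100L, 40L)),
             labels = rep(c("a", "b"), each = n_per), validate = FALSE)
}

test_that("clustering saturates, finds exhaustive medoids, and splits bundles", {
  t <- two_bundle_tract()
  # saturation: k = n gives singleton clusters, each its own prototype
  m <- cluster_streamlines(t, k = n_streamlines(t), seed = 1)
  expect_equal(m$k, 40L)
  expect_identical(sort(unname(m$prototypes)), 1:40)
  # k = 1: prototype equals the brute-force medoid over all pairs
  sub <- 1:30
  m1 <- cluster_streamlines(t, ids = sub, k = 1, seed = 2)
  D <- matrix(0, 30, 30)
  for (i in sub) for (j in sub) D[i, j] <- mdf_distance(t$streamlines[[i]],
                                                        t$streamlines[[j]])
  expect_identical(unname(m1$prototypes), sub[which.min(colSums(D))])
  # two far-separated bundles, k = 2: partition matches the labels
  m2 <- cluster_streamlines(t, k = 2, seed = 3)
  lab <- tract_labels(t)$label
  expect_equal(m2$k, 2L)
  expect_length(unique(m2$assignment[lab == "a"]), 1L)
  expect_length(unique(m2$assignment[lab == "b"]), 1L)
  expect_false(m2$assignment[[1]] == m2$assignment[[40]])
  # members are MDF-closer to their own prototype than to the other's
  protos <- m2$prototypes
  for (i in c(1, 15, 25, 40)) {
    own <- protos[[as.character(m2$assignment[[i]])]]
    other <- setdiff(unname(protos), own)
    expect_lt(mdf_distance(t$streamlines[[i]], t$streamlines[[own]]),
              mdf_distance(t$streamlines[[i]], t$streamlines[[other]]))
  }
  expect_error(cluster_streamlines(t, k = 100, seed = 1), "k")
  expect_error(cluster_streamlines(t, ids = integer(), k = 1), "non-empty")
})

test_that("clustering is deterministic given the seed", {
  t <- two_bundle_tract()
  m1 <- cluster_streamlines(t, k = 5, seed = 11)
  m2 <- cluster_streamlines(t, k = 5, seed = 11)
  expect_identical(m1$assignment, m2$assignment)
  expect_identical(m1$prototypes, m2$prototypes)
})

test_that("selection operations follow the interactive-workflow semantics", {
  t <- two_bundle_tract()
  m <- cluster_streamlines(t, k = 4, seed = 7)
  st <- selection_state(seq_len(n_streamlines(t)))
  # select_all then invert -> empty selection
  st_all <- apply_selection_op(st, m, "select_all")
  expect_identical(st_all$selected, seq_len(m$k))
  expect_identical(apply_selection_op(st_all, m, "invert")$selected, integer(0))
  # pick(c) then remove_unselected -> active ids = members(c)
  st_p <- apply_selection_op(st, m, "pick", list(cluster = 2L))
  st_r <- apply_selection_op(st_p, m, "remove_unselected")
  members <- as.integer(names(m$assignment))[m$assignment == 2L]
  expect_identical(st_r$active_ids, sort(members))
  # remove_unselected is idempotent (re-selecting the same cluster)
  st_r2 <- apply_selection_op(
    apply_selection_op(st_r, m, "pick", list(cluster = 2L)),
    m, "remove_unselected")
  expect_identical(st_r2$active_ids, st_r$active_ids)
  # expand with a radius covering all prototypes selects every cluster
  st_e <- apply_selection_op(st_p, m, "expand", list(radius = 1e6), t = t)
  expect_identical(st_e$selected, seq_len(m$k))
  expect_error(apply_selection_op(st, m, "pick", list(cluster = 99L)),
               "no such cluster")
  # history records the applied operations in order
  expect_identical(vapply(st_r$history, `[[`, "", "op"),
                   c("pick", "remove_unselected"))
})

test_that("template-guided segmentation recovers constructed wide-margin truth", {
  t <- two_bundle_tract(n_per = 40, sep = 100, sd = 1.5, seed = 21)
  lab <- tract_labels(t)$label
  template <- list(straight_streamline(c(20, 10, 10), c(20, 90, 10), 12))
  policy <- list(tau_select = 15, tau_final = 8, k_schedule = c(4L, 8L, 16L))
  ids <- auto_segment_by_template(t, template, policy, seed = 2)
  expect_identical(ids, which(lab == "a"))
  # agreement with the per-streamline MDF oracle
  d <- vapply(t$streamlines, mdf_oracle, 0, b = template[[1]])
  expect_identical(ids, which(d < 8))
  # self-template with generous thresholds retains everything
  all_ids <- auto_segment_by_template(
    t, t$streamlines, list(tau_select = 1e6, tau_final = 1e6,
                           k_schedule = c(4L)), seed = 3)
  expect_identical(all_ids, seq_len(n_streamlines(t)))
  # result is always a subset of the starting ids
  expect_true(all(ids %in% seq_len(n_streamlines(t))))
  # empty tractogram -> empty selection, no error
  empty <- tractogram(list(), ref_grid(c(10L, 10L, 10L)))
  expect_identical(auto_segment_by_template(empty, template, policy, seed = 1),
                   integer(0))
})
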