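# Shared fixtures and independent oracles. Everything here is deliberately
# naive (loops, dense sampling, closed forms) and independent of the
# vectorized / compiled implementation paths it checks.

straight_streamline <- function(from, to, n = 2) {
  cbind(seq(from[1], to[1], length.out = n),
        seq(from[2], to[2], length.out = n),
        seq(from[3], to[3], length.out = n))
}

random_polyline <- function(n_points = 10, scale = 20, origin = c(0, 0, 0)) {
  steps <- matrix(rnorm(3 * (n_points - 1), sd = scale / n_points), ncol = 3)
  pts <- rbind(origin, sweep(apply(steps, 2, cumsum), 2, origin, "+"))
  unname(pts)
}

random_tractogram <- function(n = 20, grid = ref_grid(c(40L, 40L, 40L)),
                              n_points = 8, scale = 25) {
  sl <- lapply(seq_len(n), function(i) {
    random_polyline(n_points, scale, origin = runif(3, 8, 32))
  })
  tractogram(sl, grid, validate = FALSE)
}

# arc-length walk at a fine spacing; independent of supersample_streamline
dense_walk <- function(s, spacing = 0.01) {
  out <- s[1, , drop = FALSE]
  for (i in seq_len(nrow(s) - 1)) {
    a <- s[i, ]; b <- s[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / spacing))
    lam <- seq_len(k) / k
    out <- rbind(out, outer(lam, b - a) + matrix(a, k, 3, byrow = TRUE))
  }
  out
}

# pure-R MDF oracle (direct vs flipped mean pointwise distance)
mdf_oracle <- function(a, b, n_points = 20) {
  ra <- resample_streamline_points(a, n_points)
  rb <- resample_streamline_points(b, n_points)
  direct <- mean(sqrt(rowSums((ra - rb)^2)))
  flip <- mean(sqrt(rowSums((ra - rb[n_points:1, ])^2)))
  min(direct, flip)
}

# percentile by the textbook linear-interpolation rule on the sorted sample
percentile_oracle <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# independent exposed-face counter: loop over flagged voxels, inspect the
# six neighbors
face_count_oracle <- function(arr) {
  idx <- which(arr, arr.ind = TRUE)
  d <- dim(arr)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  faces <- 0L
  for (r in seq_len(nrow(idx))) {
    for (s in seq_len(6)) {
      nb <- idx[r, ] + shifts[s, ]
      if (any(nb < 1) || any(nb > d) || !arr[nb[1], nb[2], nb[3]]) {
        faces <- faces + 1L
      }
    }
  }
  faces
}

phantom_centerline_fixture <- function() {
  rbind(c(20, 80, 40), c(22, 60, 55), c(24, 40, 50), c(25, 30, 35))
}

# small phantom setups for fast end-to-end tests
small_bundle_specs <- function(n = 60, ...) default_bundle_specs(n_streamlines = n, ...)

small_artefact_specs <- function(n = 20, background = 100) {
  default_artefact_specs(counts = c(parietal_ending = n, u_fiber = n,
                                    dorsal_loop = n, projection_vertical = n,
                                    commissural = n, background = background))
}

small_run_config <- function(n_subjects = 3, master_seed = 11) {
  cfg <- default_run_config(n_subjects = n_subjects, master_seed = master_seed)
  cfg$phantom$bundles$n_streamlines <- 60L
  cfg$phantom$artefacts <- list(parietal_ending = 20L, u_fiber = 20L,
                                dorsal_loop = 20L, projection_vertical = 20L,
                                commissural = 20L, background = 100L)
  cfg$clustering$k_schedule <- c(20L, 40L, 80L)
  cfg
}
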