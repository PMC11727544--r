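#' @useDynLib bundlescope, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats approx spline quantile sd shapiro.test t.test kmeans pt
#' @importFrom utils write.csv read.csv head tail
NULL

# Run an expression with a locally seeded RNG, restoring the caller's RNG
# state afterwards so seeded operations do not perturb the global stream.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Reference grid for a tractogram
#'
#' A reference grid ties streamline geometry (world millimetres) to a voxel
#' lattice: `dims` voxels per axis and a 4x4 affine mapping 0-based voxel
#' indices to world mm. The voxel-center convention is used throughout:
#' voxel `i` covers the half-open world region mapping back to
#' `[i - 0.5, i + 0.5)` on each axis.
#'
#' @param dims Integer vector of length 3, voxels per axis (all positive).
#' @param affine 4x4 invertible matrix, voxel index (0-based) to world mm.
#'   Defaults to the identity (1 mm isotropic, voxel i centred at world i).
#' @return An object of class `ref_grid` with fields `dims` and `affine`.
#' @export
ref_grid <- function(dims, affine = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims <= 0L)) {
    abort("`dims` must be 3 positive integers")
  }
  if (is.null(affine)) affine <- diag(4)
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || !all(is.finite(affine))) {
    abort("`affine` must be a finite 4x4 matrix")
  }
  det_a <- det(affine[1:3, 1:3, drop = FALSE])
  if (!is.finite(det_a) || abs(det_a) < 1e-12) {
    abort("`affine` must be invertible")
  }
  structure(list(dims = dims, affine = affine), class = "ref_grid")
}

#' @export
print.ref_grid <- function(x, ...) {
  cat("<ref_grid> ", paste(x$dims, collapse = " x "),
      " voxels, voxel size ",
      paste(signif(grid_voxel_size(x), 4), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

grid_voxel_size <- function(grid) {
  sqrt(colSums(grid$affine[1:3, 1:3, drop = FALSE]^2))
}

#' Map between world coordinates and voxel indices
#'
#' `world_to_voxel()` returns continuous 0-based voxel coordinates;
#' `voxel_to_world()` maps (possibly fractional) 0-based voxel coordinates to
#' world mm; `voxel_index()` snaps world points to the containing voxel under
#' the half-open voxel-center convention (`floor(v + 0.5)`).
#'
#' @param grid A [ref_grid()].
#' @param points Numeric matrix with 3 columns (world mm or voxel coords).
#' @return A numeric (or integer, for `voxel_index()`) matrix with 3 columns.
#' @export
world_to_voxel <- function(grid, points) {
  points <- rbind_points(points)
  inv <- solve(grid$affine)
  out <- cbind(points, 1) %*% t(inv)
  out[, 1:3, drop = FALSE]
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(grid, points) {
  points <- rbind_points(points)
  out <- cbind(points, 1) %*% t(grid$affine)
  out[, 1:3, drop = FALSE]
}

#' @rdname world_to_voxel
#' @export
voxel_index <- function(grid, points) {
  v <- world_to_voxel(grid, points)
  storage.mode(v) <- "double"
  idx <- floor(v + 0.5)
  storage.mode(idx) <- "integer"
  idx
}

rbind_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  if (ncol(points) != 3) abort("points must have 3 columns")
  storage.mode(points) <- "double"
  points
}

in_grid <- function(grid, idx) {
  idx[, 1] >= 0L & idx[, 1] < grid$dims[1] &
    idx[, 2] >= 0L & idx[, 2] < grid$dims[2] &
    idx[, 3] >= 0L & idx[, 3] < grid$dims[3]
}

validate_streamline <- function(m, id = NULL) {
  where <- if (is.null(id)) "streamline" else sprintf("streamline %s", id)
  if (!is.matrix(m) || ncol(m) != 3) {
    abort(sprintf("%s: must be a numeric matrix with 3 columns", where))
  }
  if (nrow(m) < 2) abort(sprintf("%s: needs at least 2 points", where))
  if (!all(is.finite(m))) abort(sprintf("%s: coordinates must be finite", where))
  seg <- diff(m)
  if (any(rowSums(seg * seg) == 0)) {
    abort(sprintf("%s: consecutive points must be distinct", where))
  }
  invisible(m)
}

#' Tractogram: a set of streamlines on a reference grid
#'
#' A tractogram holds streamlines as a list of n x 3 matrices of world-mm
#' coordinates, a [ref_grid()], and optional per-streamline labels (bundle
#' name or artefact class). Streamline ids are their positions `1..n`.
#'
#' @param streamlines List of numeric matrices (>= 2 rows, 3 columns, finite,
#'   consecutive points distinct).
#' @param grid A [ref_grid()].
#' @param labels Optional. Either a character vector of length
#'   `length(streamlines)` (possibly with `NA` for unlabeled) or a data frame
#'   with columns `id` and `label` covering a subset of ids.
#' @param validate Set to `FALSE` to skip per-streamline validation when the
#'   caller guarantees validity (used internally on large tractograms).
#' @return An object of class `tractogram`.
#' @export
tractogram <- function(streamlines, grid, labels = NULL, validate = TRUE) {
  if (!inherits(grid, "ref_grid")) abort("`grid` must be a ref_grid")
  if (!is.list(streamlines)) abort("`streamlines` must be a list of matrices")
  if (validate && length(streamlines)) {
    for (i in seq_along(streamlines)) {
      validate_streamline(streamlines[[i]], i)
    }
  }
  labels <- normalize_labels(labels, length(streamlines))
  structure(list(streamlines = streamlines, grid = grid, labels = labels),
            class = "tractogram")
}

normalize_labels <- function(labels, n) {
  if (is.null(labels)) return(NULL)
  if (is.data.frame(labels)) {
    if (!all(c("id", "label") %in% names(labels))) {
      abort("label table needs columns `id` and `label`")
    }
    ids <- as.integer(labels$id)
    if (anyDuplicated(ids) || any(ids < 1L) || any(ids > n)) {
      abort("label ids must be unique and within 1..n")
    }
    out <- rep(NA_character_, n)
    out[ids] <- as.character(labels$label)
    return(out)
  }
  labels <- as.character(labels)
  if (length(labels) != n) {
    abort("`labels` must have one entry per streamline")
  }
  labels
}

#' @export
print.tractogram <- function(x, ...) {
  cat("<tractogram> ", length(x$streamlines), " streamlines on a ",
      paste(x$grid$dims, collapse = " x "), " grid", sep = "")
  if (!is.null(x$labels)) {
    tab <- table(x$labels, useNA = "no")
    cat("; labels: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Number of streamlines in a tractogram
#' @param t A [tractogram()].
#' @return Integer count.
#' @export
n_streamlines <- function(t) length(t$streamlines)

#' Per-streamline labels of a tractogram
#' @param t A [tractogram()].
#' @return A tibble with columns `id` and `label` (`NA` when unlabeled).
#' @export
tract_labels <- function(t) {
  tibble(id = seq_along(t$streamlines),
         label = t$labels %||% rep(NA_character_, length(t$streamlines)))
}

#' @export
as_tibble.tractogram <- function(x, ...) {
  n_pts <- vapply(x$streamlines, nrow, integer(1))
  pts <- do.call(rbind, x$streamlines)
  out <- tibble(
    id = rep.int(seq_along(x$streamlines), n_pts),
    point = sequence(n_pts),
    x = pts[, 1], y = pts[, 2], z = pts[, 3]
  )
  if (!is.null(x$labels)) out$label <- x$labels[out$id]
  out
}

#' Arc length of a streamline
#'
#' Sum of Euclidean segment lengths of the polyline, in mm.
#'
#' @param s Numeric matrix (n x 3) of world-mm points, n >= 2.
#' @return Arc length in mm (strictly positive for a valid streamline).
#' @export
streamline_arclength <- function(s) {
  validate_streamline(s)
  seg <- diff(s)
  sum(sqrt(rowSums(seg * seg)))
}

cumulative_arclength <- function(s) {
  seg <- diff(s)
  c(0, cumsum(sqrt(rowSums(seg * seg))))
}

#' Resample a streamline to k equidistant points
#'
#' Points are placed at equal arc-length spacing along the polyline; the
#' first and last points are preserved exactly.
#'
#' @param s Numeric matrix (n x 3), n >= 2.
#' @param k Integer >= 2, number of output points.
#' @return A k x 3 matrix.
#' @export
resample_streamline_points <- function(s, k) {
  validate_streamline(s)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) abort("`k` must be an integer >= 2")
  cs <- cumulative_arclength(s)
  target <- seq(0, cs[length(cs)], length.out = k)
  out <- cbind(
    approx(cs, s[, 1], xout = target, ties = "ordered")$y,
    approx(cs, s[, 2], xout = target, ties = "ordered")$y,
    approx(cs, s[, 3], xout = target, ties = "ordered")$y
  )
  out[1, ] <- s[1, ]
  out[k, ] <- s[nrow(s), ]
  out
}

#' Resample a tractogram to an exact streamline count
#'
#' Downsampling draws a uniform random subset without replacement (the
#' default); upsampling by duplication must be requested explicitly because
#' duplicated streamlines silently bias density-based measures.
#'
#' @param t A [tractogram()].
#' @param n Target streamline count (positive integer).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param allow_duplicates Permit `n > n_streamlines(t)` via duplication.
#' @return A [tractogram()] with exactly `n` streamlines (labels carried over).
#' @export
resample_tractogram_count <- function(t, n, seed, allow_duplicates = FALSE) {
  stopifnot(inherits(t, "tractogram"))
  n <- as.integer(n)
  n0 <- n_streamlines(t)
  if (is.na(n) || n <= 0L) abort("`n` must be a positive integer")
  if (n > n0 && !allow_duplicates) {
    abort(sprintf(
      "requested %d streamlines from %d; set `allow_duplicates = TRUE` to upsample",
      n, n0))
  }
  ids <- with_local_seed(seed, {
    if (n <= n0) sort(sample.int(n0, n)) else c(seq_len(n0), sample.int(n0, n - n0, replace = TRUE))
  })
  tractogram(t$streamlines[ids], t$grid,
             labels = if (!is.null(t$labels)) t$labels[ids],
             validate = FALSE)
}

#' Extract a sub-tractogram by streamline id
#'
#' @param t A [tractogram()].
#' @param ids Integer ids (1-based) to keep, in the given order.
#' @return A [tractogram()] restricted to `ids`.
#' @export
subset_tractogram <- function(t, ids) {
  ids <- as.integer(ids)
  if (length(ids) && (any(ids < 1L) || any(ids > n_streamlines(t)))) {
    abort("ids out of range")
  }
  tractogram(t$streamlines[ids], t$grid,
             labels = if (!is.null(t$labels)) t$labels[ids],
             validate = FALSE)
}

# Supersample a streamline so consecutive samples are <= spacing mm apart
# (original vertices are retained). Used for point-in-ROI tests and
# voxelization, where vertex-only testing would miss thin structures.
supersample_streamline <- function(s, spacing = 0.5) {
  cs <- cumulative_arclength(s)
  total <- cs[length(cs)]
  extra <- seq(0, total, by = spacing)
  sval <- sort(unique(c(cs, extra)))
  cbind(
    approx(cs, s[, 1], xout = sval, ties = "ordered")$y,
    approx(cs, s[, 2], xout = sval, ties = "ordered")$y,
    approx(cs, s[, 3], xout = sval, ties = "ordered")$y
  )
}

# Supersample every selected streamline of a tractogram; returns a single
# point matrix plus the owning streamline id per row.
supersample_tractogram <- function(t, ids = seq_len(n_streamlines(t)),
                                   spacing = 0.5) {
  pts <- lapply(t$streamlines[ids], supersample_streamline, spacing = spacing)
  n_pts <- vapply(pts, nrow, integer(1))
  list(points = do.call(rbind, pts), id = rep.int(as.integer(ids), n_pts))
}
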