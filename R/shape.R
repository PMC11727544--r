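# Voxel-based bundle shape measures. The comparison statistic is the
# irregularity index: the ratio of the bundle's (voxel-face) surface area to
# the lateral surface of the equivalent cylinder -- the cylinder with the
# bundle's volume and mean streamline length. An ideal cylinder scores ~1;
# streamlines deviating from the bundle's main course add exposed surface
# and raise the score, so lower irregularity means a more compact bundle.

#' Voxelize a bundle
#'
#' Flags every voxel traversed by any supersampled point (<= `spacing` mm
#' apart) of the selected streamlines, under the half-open voxel-center
#' convention.
#'
#' @param t A [tractogram()].
#' @param ids Non-empty integer vector of streamline ids.
#' @param grid Voxelization grid (default: the tractogram's own grid).
#' @param spacing Supersampling spacing, mm (default 0.5 = half a phantom
#'   voxel).
#' @return A [binary_mask()].
#' @export
voxelize_bundle <- function(t, ids, grid = t$grid, spacing = 0.5) {
  stopifnot(inherits(t, "tractogram"))
  ids <- as.integer(ids)
  if (!length(ids)) abort("cannot voxelize an empty bundle")
  ss <- supersample_tractogram(t, ids, spacing)
  idx <- voxel_index(grid, ss$points)
  if (!all(in_grid(grid, idx))) {
    abort("bundle points fall outside the voxelization grid")
  }
  arr <- array(FALSE, dim = grid$dims)
  arr[idx + 1L] <- TRUE
  binary_mask(grid, arr)
}

# count of exposed voxel faces (6-connectivity) of a logical array
exposed_faces <- function(arr) {
  d <- dim(arr)
  # crop to the bounding box (plus a 1-voxel pad) to keep the shifts cheap
  w <- which(arr, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - 1L, 1L)
  hi <- pmin(apply(w, 2, max) + 1L, d)
  a <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d <- dim(a)
  pad_shift <- function(axis, dir) {
    # neighbor occupancy shifted along `axis` by `dir`; outside is empty
    out <- array(FALSE, dim = d)
    if (axis == 1) {
      if (dir > 0) out[2:d[1], , ] <- a[1:(d[1] - 1), , , drop = FALSE]
      else out[1:(d[1] - 1), , ] <- a[2:d[1], , , drop = FALSE]
    } else if (axis == 2) {
      if (dir > 0) out[, 2:d[2], ] <- a[, 1:(d[2] - 1), , drop = FALSE]
      else out[, 1:(d[2] - 1), ] <- a[, 2:d[2], , drop = FALSE]
    } else {
      if (dir > 0) out[, , 2:d[3]] <- a[, , 1:(d[3] - 1), drop = FALSE]
      else out[, , 1:(d[3] - 1)] <- a[, , 2:d[3], drop = FALSE]
    }
    out
  }
  faces <- 0L
  for (axis in 1:3) {
    for (dir in c(-1L, 1L)) {
      faces <- faces + sum(a & !pad_shift(axis, dir))
    }
  }
  faces
}

#' Shape measures of a segmented bundle
#'
#' Computes, from the selected streamlines and their voxelization:
#' \describe{
#'   \item{mean_length}{mean streamline arc length (mm).}
#'   \item{span}{mean endpoint-to-endpoint Euclidean distance (mm).}
#'   \item{volume}{flagged-voxel count x voxel volume (mm^3).}
#'   \item{surface_area}{exposed voxel faces (6-connectivity) x face area
#'     (mm^2).}
#'   \item{diameter}{of the equivalent cylinder,
#'     `2 * sqrt(volume / (pi * mean_length))` (mm).}
#'   \item{irregularity}{`surface_area / (pi * diameter * mean_length)`
#'     (dimensionless; ~1 for an ideal cylinder).}
#'   \item{curl, elongation}{`mean_length / span` and
#'     `mean_length / diameter` (derived conveniences).}
#' }
#'
#' @param t A [tractogram()].
#' @param ids Non-empty integer vector of streamline ids.
#' @param grid Voxelization grid (default: the tractogram's).
#' @param spacing Supersampling spacing, mm.
#' @param subject_id,bundle,method Optional metadata columns carried into
#'   the output row.
#' @return A one-row tibble with the measures above plus `n_streamlines`
#'   and any metadata supplied.
#' @export
bundle_shape_measures <- function(t, ids, grid = t$grid, spacing = 0.5,
                                  subject_id = NULL, bundle = NULL,
                                  method = NULL) {
  ids <- as.integer(ids)
  if (!length(ids)) abort("cannot measure an empty segmentation")
  lens <- vapply(t$streamlines[ids], streamline_arclength, numeric(1))
  mean_length <- mean(lens)
  if (mean_length <= 0) abort("degenerate segmentation: zero mean length")
  span <- mean(vapply(t$streamlines[ids], function(s) {
    sqrt(sum((s[nrow(s), ] - s[1, ])^2))
  }, numeric(1)))
  mask <- voxelize_bundle(t, ids, grid, spacing)
  vs <- grid_voxel_size(grid)
  voxel_volume <- prod(vs)
  # face area of the (isotropic) voxel; anisotropic grids use the mean face
  face_area <- mean(c(vs[1] * vs[2], vs[1] * vs[3], vs[2] * vs[3]))
  volume <- sum(mask$array) * voxel_volume
  surface_area <- exposed_faces(mask$array) * face_area
  diameter <- 2 * sqrt(volume / (pi * mean_length))
  irregularity <- surface_area / (pi * diameter * mean_length)
  out <- tibble(
    n_streamlines = length(ids),
    mean_length = mean_length,
    span = span,
    volume = volume,
    surface_area = surface_area,
    diameter = diameter,
    irregularity = irregularity,
    curl = mean_length / span,
    elongation = mean_length / diameter
  )
  meta <- tibble(.rows = 1)
  if (!is.null(subject_id)) meta$subject_id <- subject_id
  if (!is.null(bundle)) meta$bundle <- bundle
  if (!is.null(method)) meta$method <- method
  dplyr::bind_cols(meta, out)
}
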