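# ROI-based bundle extraction: logical streamline filters over binary masks,
# parametric axis-aligned boxes, and slice (plane) filters, composed into
# per-bundle recipes. Semantics follow the classical virtual-dissection
# workflow: each ROI term supports the logical operator 'Any Part' (the
# streamline must touch the region) or 'No Part' (it must not), terms are
# combined by conjunction, and a midline slice filter discards commissural
# crossers. Streamlines are supersampled at <= 0.5 mm before point-in-region
# tests so thin ROIs pierced between vertices are not missed.

#' ROI filter terms
#'
#' `roi_box()` builds a parametric axis-aligned box in world mm (the
#' reproducible analog of a hand-drawn ROI); `roi_mask()` wraps a
#' [binary_mask()]. Both carry the logical operator: `"any_part"` keeps
#' streamlines touching the region, `"no_part"` discards them.
#'
#' @param xlim,ylim,zlim Numeric length-2 extents in world mm (box).
#' @param logic `"any_part"` or `"no_part"`.
#' @param name Optional term name (used in printing).
#' @return An object of class `roi_term`.
#' @export
roi_box <- function(xlim, ylim, zlim, logic = c("any_part", "no_part"),
                    name = NULL) {
  logic <- match.arg(logic)
  lim <- rbind(sort(as.numeric(xlim)), sort(as.numeric(ylim)),
               sort(as.numeric(zlim)))
  if (any(lim[, 2] <= lim[, 1])) abort("box extents must be positive")
  structure(list(kind = "box", lim = lim, logic = logic,
                 center = rowMeans(lim), half = (lim[, 2] - lim[, 1]) / 2,
                 name = name),
            class = "roi_term")
}

#' @rdname roi_box
#' @param mask A [binary_mask()]. Inclusion (`any_part`) masks must be
#'   non-empty.
#' @export
roi_mask <- function(mask, logic = c("any_part", "no_part"), name = NULL) {
  logic <- match.arg(logic)
  stopifnot(inherits(mask, "binary_mask"))
  if (logic == "any_part" && !any(mask$array)) {
    warn("inclusion ROI mask is empty; it can never match")
  }
  structure(list(kind = "mask", mask = mask, logic = logic, name = name),
            class = "roi_term")
}

#' Slice filter: exclude streamlines crossing a plane
#'
#' A streamline "crosses" the plane when it has points strictly on both
#' sides; points lying exactly on the plane belong to neither side, so a
#' streamline merely touching the plane is not a crosser.
#'
#' @param axis `"x"`, `"y"`, or `"z"`.
#' @param coordinate Plane position in world mm.
#' @return An object of class `slice_filter`.
#' @export
slice_filter <- function(axis = c("x", "y", "z"), coordinate) {
  axis <- match.arg(axis)
  structure(list(kind = "slice", axis = match(axis, c("x", "y", "z")),
                 coordinate = as.numeric(coordinate),
                 mode = "exclude_crossing"),
            class = "slice_filter")
}

#' Bundle recipe: an ordered conjunction of filter terms
#'
#' @param name Bundle name.
#' @param terms List of [roi_box()] / [roi_mask()] terms and
#'   [slice_filter()]s. At least one inclusion (`any_part`) term is
#'   required.
#' @return An object of class `bundle_recipe`.
#' @export
bundle_recipe <- function(name, terms) {
  if (!length(terms)) abort("recipe needs at least one term")
  is_incl <- vapply(terms, function(tm) {
    inherits(tm, "roi_term") && tm$logic == "any_part"
  }, logical(1))
  if (!any(is_incl)) abort("recipe needs at least one inclusion (any_part) term")
  structure(list(name = name, terms = terms), class = "bundle_recipe")
}

#' @export
print.bundle_recipe <- function(x, ...) {
  cat("<bundle_recipe> ", x$name, ": ", length(x$terms), " terms\n", sep = "")
  for (tm in x$terms) {
    if (inherits(tm, "slice_filter")) {
      cat("  slice ", c("x", "y", "z")[tm$axis], " = ", tm$coordinate,
          " (exclude crossers)\n", sep = "")
    } else if (tm$kind == "box") {
      cat("  ", tm$logic, " box [",
          paste(apply(tm$lim, 1, function(r) paste(signif(r, 4), collapse = ",")),
                collapse = "] x ["), "]",
          if (!is.null(tm$name)) paste0("  (", tm$name, ")"), "\n", sep = "")
    } else {
      cat("  ", tm$logic, " mask (", sum(tm$mask$array), " voxels)\n", sep = "")
    }
  }
  invisible(x)
}

points_in_term <- function(points, term, grid) {
  if (term$kind == "box") {
    lim <- term$lim
    points[, 1] >= lim[1, 1] & points[, 1] <= lim[1, 2] &
      points[, 2] >= lim[2, 1] & points[, 2] <= lim[2, 2] &
      points[, 3] >= lim[3, 1] & points[, 3] <= lim[3, 2]
  } else {
    mg <- term$mask$grid
    if (!identical(mg$dims, grid$dims) ||
        max(abs(mg$affine - grid$affine)) > 1e-4) {
      abort("ROI mask grid does not match the tractogram grid")
    }
    idx <- voxel_index(mg, points)
    ok <- in_grid(mg, idx)
    hit <- logical(nrow(points))
    hit[ok] <- term$mask$array[idx[ok, , drop = FALSE] + 1L]
    hit
  }
}

#' Does a streamline satisfy an ROI term?
#'
#' The streamline is supersampled at <= 0.5 mm spacing (vertices plus
#' intermediate segment points); `any_part` is true iff any sample falls in
#' the region, `no_part` is its negation.
#'
#' @param s Streamline matrix (n x 3, world mm).
#' @param roi An [roi_box()] / [roi_mask()] term.
#' @param grid The tractogram's [ref_grid()].
#' @param spacing Supersampling spacing, mm.
#' @return Logical scalar.
#' @export
streamline_in_roi <- function(s, roi, grid, spacing = 0.5) {
  stopifnot(inherits(roi, "roi_term"))
  pts <- supersample_streamline(rbind_points(s), spacing)
  touched <- any(points_in_term(pts, roi, grid))
  if (roi$logic == "any_part") touched else !touched
}

#' Does a streamline cross a slice plane?
#'
#' @param s Streamline matrix.
#' @param f A [slice_filter()].
#' @return `TRUE` iff the streamline has points strictly on both sides of
#'   the plane.
#' @export
streamline_crosses_slice <- function(s, f) {
  stopifnot(inherits(f, "slice_filter"))
  v <- rbind_points(s)[, f$axis]
  any(v > f$coordinate) && any(v < f$coordinate)
}

#' Apply a bundle recipe to a tractogram
#'
#' Returns the ids of streamlines satisfying every term of the recipe
#' (conjunction); slice filters exclude crossers. `apply_recipes()` applies
#' several recipes while supersampling the tractogram only once.
#'
#' @param t A [tractogram()].
#' @param recipe A [bundle_recipe()].
#' @param spacing Supersampling spacing, mm.
#' @return Sorted integer vector of streamline ids.
#' @export
apply_recipe <- function(t, recipe, spacing = 0.5) {
  apply_recipes(t, list(recipe), spacing)[[1]]
}

#' @rdname apply_recipe
#' @param recipes A list of [bundle_recipe()]s.
#' @return For `apply_recipes()`: a named list of id vectors.
#' @export
apply_recipes <- function(t, recipes, spacing = 0.5) {
  stopifnot(inherits(t, "tractogram"))
  for (r in recipes) stopifnot(inherits(r, "bundle_recipe"))
  n <- n_streamlines(t)
  if (n == 0L) {
    out <- rep(list(integer()), length(recipes))
    names(out) <- vapply(recipes, function(r) r$name, character(1))
    return(out)
  }
  ss <- supersample_tractogram(t, spacing = spacing)
  sid <- ss$id
  out <- lapply(recipes, function(recipe) {
    keep <- rep(TRUE, n)
    for (term in recipe$terms) {
      if (inherits(term, "slice_filter")) {
        v <- ss$points[, term$axis]
        pos <- rowsum((v > term$coordinate) + 0, sid) > 0
        neg <- rowsum((v < term$coordinate) + 0, sid) > 0
        keep <- keep & !(as.vector(pos) & as.vector(neg))
      } else {
        hit <- points_in_term(ss$points, term, t$grid)
        touched <- as.vector(rowsum(hit + 0, sid) > 0)
        keep <- keep & (if (term$logic == "any_part") touched else !touched)
      }
    }
    which(keep)
  })
  names(out) <- vapply(recipes, function(r) r$name, character(1))
  out
}

deform_term <- function(term, def) {
  if (is.null(def) || inherits(term, "slice_filter") || term$kind != "box") {
    return(term)
  }
  ctr <- as.vector(apply_deformation(matrix(term$center, 1), def))
  lim <- cbind(ctr - term$half, ctr + term$half)
  term$lim <- lim
  term$center <- ctr
  term
}

#' Default ROI recipes for the four phantom bundles
#'
#' Encodes the segmentation heuristics for the phantom geometry:
#' \describe{
#'   \item{AF}{a coronal inclusion box in the deep white matter at the level
#'     of the arc's longitudinal portion plus an axial inclusion box in the
#'     temporal descent, both `any_part`; an exclusion block at the level of
#'     the insula (removing vertical projection-like streamlines); midline
#'     slice filter.}
#'   \item{AF_ant}{the same coronal inclusion; the axial ROI enlarged to a
#'     full plane segregating temporal from parietal terminations, as
#'     `no_part`; midline filter.}
#'   \item{AF_post}{the same axial inclusion; the coronal ROI enlarged to a
#'     full plane segregating frontal terminations, as `no_part`; midline
#'     filter.}
#'   \item{IFOF}{a coronal stem inclusion box (external/extreme-capsule
#'     analog) plus dorsal and ventral exclusion boxes above and below the
#'     stem; with `ifof_extended = TRUE` (default) the exclusions are
#'     extended to the axial plane, catching streamlines that loop back
#'     dorsally toward the frontal cortex and ILF-like returns; midline
#'     filter.}
#' }
#' Box coordinates are expressed for the undeformed phantom anatomy; when a
#' subject `deformation` is given the box centers follow it (the analog of
#' drawing ROIs on each patient's own anatomy).
#'
#' @param grid A [ref_grid()] (used for the plane extents).
#' @param deformation Optional subject [deformation()].
#' @param ifof_extended Use the extended IFOF exclusion ROIs (default).
#' @param insula_exclusion Include the AF insula exclusion block (default).
#' @return Named list of [bundle_recipe()]s (`AF`, `AF_ant`, `AF_post`,
#'   `IFOF`).
#' @export
default_recipes <- function(grid = phantom_grid(), deformation = NULL,
                            ifof_extended = TRUE, insula_exclusion = TRUE) {
  gx <- grid$dims[1] - 1
  gy <- grid$dims[2] - 1
  gz <- grid$dims[3] - 1
  midline <- slice_filter("x", PHANTOM_MIDLINE_X)
  af_coronal <- roi_box(c(44, 72), c(97, 103), c(88, 124), "any_part",
                        name = "AF coronal waypoint")
  af_axial <- roi_box(c(44, 72), c(72, 98), c(47, 53), "any_part",
                      name = "AF axial temporal waypoint")
  insula <- roi_box(c(60, 82), c(92, 112), c(55, 80), "no_part",
                    name = "insula exclusion")
  # enlarged planes for the segment recipes (full extent in two axes)
  axial_plane <- roi_box(c(0, PHANTOM_MIDLINE_X), c(0, gy), c(47, 53),
                         "no_part", name = "temporo-parietal segregation plane")
  coronal_plane <- roi_box(c(0, PHANTOM_MIDLINE_X), c(97, 103), c(0, gz),
                           "no_part", name = "fronto-parietal segregation plane")
  stem <- roi_box(c(51, 73), c(107, 113), c(51, 73), "any_part",
                  name = "IFOF stem waypoint")
  ifof_dorsal <- roi_box(c(44, 82), c(107, 113), c(76, 104), "no_part",
                         name = "IFOF dorsal exclusion")
  ifof_ventral <- roi_box(c(44, 82), c(107, 113), c(24, 50), "no_part",
                          name = "IFOF ventral exclusion")
  ifof_dorsal_ext <- roi_box(c(44, 82), c(95, 160), c(104, 126), "no_part",
                             name = "IFOF dorsal exclusion, axial extension")
  ifof_ventral_ext <- roi_box(c(44, 82), c(114, 160), c(28, 46), "no_part",
                              name = "IFOF ventral exclusion, axial extension")
  af_terms <- list(af_coronal, af_axial)
  if (insula_exclusion) af_terms <- c(af_terms, list(insula))
  ifof_terms <- list(stem, ifof_dorsal, ifof_ventral)
  if (ifof_extended) {
    ifof_terms <- c(ifof_terms, list(ifof_dorsal_ext, ifof_ventral_ext))
  }
  recipes <- list(
    AF = bundle_recipe("AF", c(af_terms, list(midline))),
    AF_ant = bundle_recipe("AF_ant", list(af_coronal, axial_plane, midline)),
    AF_post = bundle_recipe("AF_post", list(af_axial, coronal_plane, midline)),
    IFOF = bundle_recipe("IFOF", c(ifof_terms, list(midline)))
  )
  if (!is.null(deformation)) {
    recipes <- lapply(recipes, function(r) {
      r$terms <- lapply(r$terms, deform_term, def = deformation)
      r
    })
  }
  recipes
}
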