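# Streamline-based segmentation: the minimum-average-direct-flip (MDF)
# metric, dissimilarity-embedding clustering with medoid prototypes, the
# interactive selection operations (pick / invert / remove-unselected /
# select-all / expand), and a scripted template-guided policy that stands in
# for an operator's iterative visual selection.

#' Distance configuration for the MDF metric
#'
#' @param n_points Number of equidistant points each streamline is resampled
#'   to before computing MDF (default 20, the standard choice for
#'   direct-flip metrics).
#' @return An object of class `distance_config`.
#' @export
distance_config <- function(n_points = 20) {
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L) abort("`n_points` must be >= 2")
  structure(list(n_points = n_points), class = "distance_config")
}

# flatten streamlines to rows of (x1,y1,z1,...,xk,yk,zk) after resampling
mdf_matrix <- function(streamlines, cfg) {
  k <- cfg$n_points
  out <- matrix(0, length(streamlines), 3L * k)
  for (i in seq_along(streamlines)) {
    out[i, ] <- as.vector(t(resample_streamline_points(streamlines[[i]], k)))
  }
  out
}

mdf_cross <- function(A, B) .mdf_cross_cpp(A, B)

#' Minimum-average-direct-flip distance between two streamlines
#'
#' Both streamlines are resampled to `cfg$n_points` equidistant points; the
#' MDF is the smaller of the mean pointwise Euclidean distance in direct
#' point order and in reversed order, making the metric symmetric,
#' non-negative, and invariant to the arbitrary tracking direction.
#'
#' @param a,b Streamline matrices (n x 3, world mm).
#' @param cfg A [distance_config()].
#' @return Distance in mm.
#' @export
mdf_distance <- function(a, b, cfg = distance_config()) {
  A <- mdf_matrix(list(rbind_points(a)), cfg)
  B <- mdf_matrix(list(rbind_points(b)), cfg)
  as.numeric(mdf_cross(A, B))
}

# farthest-first traversal for reference streamlines of the dissimilarity
# embedding; the first reference is a seeded uniform draw
farthest_first_refs <- function(X, p) {
  n <- nrow(X)
  refs <- integer(p)
  refs[1] <- sample.int(n, 1)
  mind <- as.vector(mdf_cross(X, X[refs[1], , drop = FALSE]))
  if (p > 1) {
    for (j in 2:p) {
      refs[j] <- which.max(mind)
      d <- as.vector(mdf_cross(X, X[refs[j], , drop = FALSE]))
      mind <- pmin(mind, d)
    }
  }
  refs
}

cluster_impl <- function(X, ids, k, seed) {
  n <- length(ids)
  if (k == n) {
    assignment <- stats::setNames(seq_len(n), ids)
    prototypes <- stats::setNames(as.integer(ids), seq_len(n))
    return(structure(list(k = n, assignment = assignment,
                          prototypes = prototypes),
                     class = "cluster_model"))
  }
  cl <- with_local_seed(seed, {
    p <- min(40L, n)
    refs <- farthest_first_refs(X, p)
    E <- mdf_cross(X, X[refs, , drop = FALSE])
    k_eff <- min(k, nrow(unique(E)))
    stats::kmeans(E, centers = k_eff, iter.max = 100L, nstart = 1L)$cluster
  })
  # renumber to consecutive non-empty clusters
  cl <- match(cl, sort(unique(cl)))
  n_cl <- max(cl)
  prototypes <- integer(n_cl)
  for (c in seq_len(n_cl)) {
    members <- which(cl == c)
    if (length(members) == 1L) {
      prototypes[c] <- ids[members]
    } else {
      D <- mdf_cross(X[members, , drop = FALSE], X[members, , drop = FALSE])
      prototypes[c] <- ids[members[which.min(colSums(D))]]
    }
  }
  structure(list(k = n_cl,
                 assignment = stats::setNames(cl, ids),
                 prototypes = stats::setNames(prototypes, seq_len(n_cl))),
            class = "cluster_model")
}

#' Cluster streamlines with medoid prototypes
#'
#' Streamlines are embedded by their MDF distances to `min(40, n)` reference
#' streamlines chosen by farthest-first traversal, partitioned by k-means on
#' the embedding, and each cluster is summarized by its medoid prototype
#' (the member minimizing the summed MDF to its co-members) -- the
#' dissimilarity-representation design used by interactive streamline
#' segmentation tools. Deterministic given `seed`.
#'
#' @param t A [tractogram()].
#' @param ids Streamline ids to cluster (default: all).
#' @param k Requested number of clusters (`1 <= k <= length(ids)`); up to
#'   `k` non-empty clusters are returned.
#' @param cfg A [distance_config()].
#' @param seed Integer seed.
#' @return An object of class `cluster_model` with fields `k`,
#'   `assignment` (named map id -> cluster index) and `prototypes` (named
#'   map cluster index -> medoid id).
#' @export
cluster_streamlines <- function(t, ids = seq_len(n_streamlines(t)), k,
                                cfg = distance_config(), seed = NULL) {
  stopifnot(inherits(t, "tractogram"))
  ids <- as.integer(ids)
  if (!length(ids)) abort("`ids` must be non-empty")
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > length(ids)) {
    abort(sprintf("`k` must be in 1..%d", length(ids)))
  }
  X <- mdf_matrix(t$streamlines[ids], cfg)
  cluster_impl(X, ids, k, seed)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> ", x$k, " clusters over ", length(x$assignment),
      " streamlines\n", sep = "")
  invisible(x)
}

#' Selection state over a cluster model
#'
#' Mirrors the interactive workflow of prototype-based segmentation:
#' a set of active streamline ids, a set of selected cluster indices, and
#' the history of applied operations.
#'
#' @param active_ids Integer ids currently retained.
#' @param selected Integer cluster indices currently selected.
#' @return An object of class `selection_state`.
#' @export
selection_state <- function(active_ids, selected = integer()) {
  structure(list(active_ids = as.integer(active_ids),
                 selected = as.integer(selected),
                 history = list()),
            class = "selection_state")
}

#' Apply an interactive selection operation
#'
#' The five operations of prototype-based interactive segmentation:
#' `pick` adds a cluster to the selection, `invert` complements the
#' selection within the current clusters, `remove_unselected` shrinks the
#' active ids to the members of selected clusters (and clears the
#' selection), `select_all` selects every cluster, and `expand` adds all
#' clusters whose prototype lies within `args$radius` mm (MDF) of any
#' selected prototype.
#'
#' @param state A [selection_state()].
#' @param model A [cluster_model][cluster_streamlines()].
#' @param op One of `"pick"`, `"invert"`, `"remove_unselected"`,
#'   `"select_all"`, `"expand"`.
#' @param args Operation arguments: `cluster` for `pick`; `radius` (mm) and
#'   optionally `t`/`cfg` for `expand`.
#' @param t,cfg Tractogram and [distance_config()] (needed by `expand` to
#'   compute prototype MDF distances).
#' @return The updated [selection_state()].
#' @export
apply_selection_op <- function(state, model, op = c("pick", "invert",
                                                    "remove_unselected",
                                                    "select_all", "expand"),
                               args = list(), t = NULL,
                               cfg = distance_config()) {
  op <- match.arg(op)
  clusters <- seq_len(model$k)
  new_state <- state
  if (op == "pick") {
    cl <- as.integer(args$cluster)
    if (!length(cl) || any(!cl %in% clusters)) {
      abort("pick: no such cluster")
    }
    new_state$selected <- sort(union(state$selected, cl))
  } else if (op == "invert") {
    new_state$selected <- setdiff(clusters, state$selected)
  } else if (op == "select_all") {
    new_state$selected <- clusters
  } else if (op == "remove_unselected") {
    member_of <- model$assignment[as.character(state$active_ids)]
    keep <- state$active_ids[member_of %in% state$selected]
    new_state$active_ids <- sort(keep)
    new_state$selected <- integer()
  } else if (op == "expand") {
    if (is.null(args$radius)) abort("expand: needs args$radius (mm)")
    if (is.null(t)) abort("expand: needs the tractogram `t`")
    if (!length(state$selected)) {
      new_state$selected <- state$selected
    } else {
      proto_ids <- model$prototypes
      P <- mdf_matrix(t$streamlines[proto_ids], cfg)
      sel_rows <- which(as.integer(names(proto_ids)) %in% state$selected)
      D <- mdf_cross(P, P[sel_rows, , drop = FALSE])
      near <- which(apply(D, 1, min) <= args$radius)
      new_state$selected <- sort(union(state$selected, near))
    }
  }
  new_state$history <- c(state$history, list(list(op = op, args = args)))
  new_state
}

#' Template-guided streamline segmentation
#'
#' A scripted surrogate for the operator's iterative select / clean /
#' re-cluster workflow: the active set is clustered with an increasing
#' cluster-count schedule; after each round, clusters whose medoid prototype
#' lies within `tau_select` mm (MDF) of the nearest template streamline are
#' kept and the rest removed; iteration stops when the schedule is exhausted
#' or the cluster count reaches the active-set size (each streamline its own
#' representative). Finally, individual streamlines farther than `tau_final`
#' mm from every template are dropped. Deterministic given `seed`.
#'
#' @param t A [tractogram()].
#' @param template Non-empty list of template streamlines (matrices), e.g. a
#'   bundle centerline or exemplar streamlines.
#' @param policy List with `tau_select` (mm, default 15), `k_schedule`
#'   (default `c(50, 100, 200, 400)`), `tau_final` (mm, default 8).
#' @param cfg A [distance_config()].
#' @param seed Integer seed.
#' @param ids Ids to start from (default: all).
#' @return Sorted integer vector of selected streamline ids (empty for an
#'   empty tractogram).
#' @export
auto_segment_by_template <- function(t, template,
                                     policy = list(), cfg = distance_config(),
                                     seed = NULL,
                                     ids = seq_len(n_streamlines(t))) {
  stopifnot(inherits(t, "tractogram"))
  if (is.matrix(template)) template <- list(template)
  if (!length(template)) abort("`template` must be non-empty")
  tau_select <- policy$tau_select %||% 15
  tau_final <- policy$tau_final %||% 8
  k_schedule <- policy$k_schedule %||% c(50L, 100L, 200L, 400L)
  active <- sort(as.integer(ids))
  if (!length(active)) return(integer())
  Tm <- mdf_matrix(template, cfg)
  X_all <- mdf_matrix(t$streamlines[active], cfg)
  rownames(X_all) <- as.character(active)
  step <- 0L
  for (k in k_schedule) {
    if (k >= length(active)) break
    step <- step + 1L
    X <- X_all[as.character(active), , drop = FALSE]
    model <- cluster_impl(X, active, as.integer(k),
                          seed = if (is.null(seed)) NULL else seed + step)
    P <- mdf_matrix(t$streamlines[model$prototypes], cfg)
    d_proto <- apply(mdf_cross(P, Tm), 1, min)
    selected <- which(d_proto < tau_select)
    if (!length(selected)) {
      active <- integer()
      break
    }
    st <- selection_state(active, selected)
    st <- apply_selection_op(st, model, "remove_unselected")
    active <- st$active_ids
  }
  if (!length(active)) return(integer())
  X <- X_all[as.character(active), , drop = FALSE]
  d_final <- apply(mdf_cross(X, Tm), 1, min)
  sort(active[d_final < tau_final])
}
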