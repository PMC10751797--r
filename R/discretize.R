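# State assignment: map every trajectory frame to a discrete conformational
# state.  Three routes are supported, mirroring common practice for torsion
# -space progress coordinates:
#   * rectilinear bins + state points (a bin containing a state point IS that
#     state; other bins are unassigned),
#   * an arbitrary user assignment hook,
#   * a two-stage cluster-then-classify scheme for large data sets
#     (average-linkage agglomerative clustering on a subset, then a
#     k-nearest-neighbour classifier for the remainder).

UNASSIGNED <- -1L

#' Remap periodic coordinates to a new base interval
#'
#' Shifts each value by whole periods until it lies in
#' `[new_min, new_min + period)`.  Used to move the branch cut of periodic
#' torsion angles away from populated regions (e.g. phi angles in
#' `[-180, 180)` remapped to `[-210, 150)`) so that plain Euclidean
#' distances are valid afterwards.
#'
#' @param angles Numeric vector (or matrix column) of periodic values.
#' @param period Period of the coordinate (e.g. 360 for degrees); must be
#'   positive.
#' @param new_min Lower edge of the destination interval.
#' @return Numeric vector of the same length, order preserved.
#' @examples
#' remap_periodic(160, 360, -210)  # -200
#' @export
remap_periodic <- function(angles, period, new_min) {
  if (period <= 0) stop("period must be positive")
  ((angles - new_min) %% period) + new_min
}

#' Define a rectilinear state map
#'
#' States are declared by per-dimension bin edges plus one representative
#' point per state: the bin a point falls into becomes that state.  Bins
#' containing no state point are unassigned territory.
#'
#' @param bin_edges List of strictly increasing numeric vectors, one per
#'   feature dimension.
#' @param state_points Named list mapping state id (as a name, e.g. `"0"`) to
#'   the state's representative coordinate vector.
#' @param source_id,target_id Integer ids of the source and target states;
#'   must differ and must both appear in `state_points`.
#' @param periodic_shift Optional list of per-dimension
#'   `list(period =, new_min =)` remaps (or `NULL` entries) applied to
#'   features before binning, see [remap_periodic()].
#' @return An object of class `state_map`.
#' @export
state_map_rectilinear <- function(bin_edges, state_points, source_id,
                                  target_id, periodic_shift = NULL) {
  if (!is.list(bin_edges) || length(bin_edges) == 0)
    stop("bin_edges must be a non-empty list of numeric vectors")
  for (d in seq_along(bin_edges)) {
    e <- bin_edges[[d]]
    if (length(e) < 2 || any(diff(e) <= 0))
      stop("bin edges must be strictly increasing (dimension ", d, ")")
  }
  ids <- as.integer(names(state_points))
  if (any(is.na(ids))) stop("state_points must be named by integer state ids")
  source_id <- as.integer(source_id); target_id <- as.integer(target_id)
  if (source_id == target_id) stop("source and target states must differ")
  if (!all(c(source_id, target_id) %in% ids))
    stop("source and target ids must appear in state_points")
  ndim <- length(bin_edges)
  bins <- t(vapply(seq_along(state_points), function(s) {
    p <- state_points[[s]]
    if (length(p) != ndim) stop("state point dimensionality mismatch")
    vapply(seq_len(ndim), function(d) {
      e <- bin_edges[[d]]
      b <- findInterval(p[d], e, rightmost.closed = TRUE)
      if (b < 1 || b > length(e) - 1)
        stop("state point for state ", names(state_points)[s],
             " falls outside the bin grid")
      as.integer(b)
    }, 0L)
  }, integer(ndim)))
  if (ndim == 1) bins <- matrix(bins, ncol = 1)
  keys <- apply(bins, 1, paste, collapse = ",")
  if (anyDuplicated(keys))
    stop("configuration error: two state points share a bin (",
         keys[duplicated(keys)][1], ")")
  structure(list(mode = "rectilinear", bin_edges = bin_edges,
                 state_ids = ids, state_bins = bins, bin_keys = keys,
                 source_id = source_id, target_id = target_id,
                 periodic_shift = periodic_shift),
            class = "state_map")
}

#' @export
print.state_map <- function(x, ...) {
  cat("<state_map> mode=", x$mode, ", ", length(x$state_ids), " states",
      " (source=", x$source_id, ", target=", x$target_id, ")\n", sep = "")
  invisible(x)
}

# Apply a state map's periodic shifts to a feature matrix.
.apply_periodic <- function(features, periodic_shift) {
  if (is.null(periodic_shift)) return(features)
  for (d in seq_along(periodic_shift)) {
    ps <- periodic_shift[[d]]
    if (!is.null(ps))
      features[, d] <- remap_periodic(features[, d], ps$period, ps$new_min)
  }
  features
}

#' Assign frames to states with a rectilinear state map
#'
#' @param features Numeric matrix, one row per frame, columns matching the
#'   state map's bin-edge dimensions (a vector is accepted for 1-D maps).
#' @param map A `state_map` from [state_map_rectilinear()].
#' @return Integer vector of per-frame state ids; frames in bins without a
#'   state point receive the unassigned sentinel `-1`.  A frame outside the
#'   grid is an error naming the frame index.
#' @export
assign_rectilinear <- function(features, map) {
  if (!inherits(map, "state_map") || map$mode != "rectilinear")
    stop("map must be a rectilinear state_map")
  if (is.vector(features)) features <- matrix(features, ncol = 1)
  ndim <- length(map$bin_edges)
  if (ncol(features) != ndim)
    stop("feature dimensionality (", ncol(features),
         ") does not match bin grid (", ndim, ")")
  features <- .apply_periodic(features, map$periodic_shift)
  n <- nrow(features)
  binmat <- matrix(0L, n, ndim)
  for (d in seq_len(ndim)) {
    e <- map$bin_edges[[d]]
    b <- findInterval(features[, d], e, rightmost.closed = TRUE)
    bad <- which(b < 1 | b > length(e) - 1)
    if (length(bad) > 0)
      stop("frame ", bad[1] - 1L, " lies outside the bin grid in dimension ",
           d, " (value ", features[bad[1], d], ")")
    binmat[, d] <- b
  }
  keys <- apply(binmat, 1, paste, collapse = ",")
  idx <- match(keys, map$bin_keys)
  labels <- ifelse(is.na(idx), UNASSIGNED, map$state_ids[idx])
  as.integer(labels)
}

#' Fit the two-stage cluster-then-classify model
#'
#' Stage one runs hierarchical agglomerative clustering (average linkage,
#' Euclidean dissimilarity) on a subset of conformations, cutting the tree at
#' `distance_threshold`.  Stage two fits a k-nearest-neighbour classifier on
#' the cluster-labelled subset; [predict_two_stage()] then labels the full
#' data set.  This avoids the memory cost of clustering every frame of a
#' large simulation.
#'
#' @param subset_features Numeric matrix of training conformations (rows =
#'   frames).  Subset selection (e.g. the final iterations of a simulation)
#'   is the caller's responsibility.
#' @param distance_threshold Height at which the average-linkage tree is cut;
#'   scale-dependent (75 is appropriate for torsion angles in degrees with
#'   well-separated free-energy basins).
#' @param n_neighbors Neighbours for the kNN stage (default 5).
#' @param linkage Agglomeration criterion; only `"average"` is supported.
#' @return An object of class `two_stage_model` with 0-based cluster
#'   `labels`, per-cluster `centroids`, and the training features.
#' @export
fit_two_stage <- function(subset_features, distance_threshold,
                          n_neighbors = 5L, linkage = "average") {
  if (!identical(linkage, "average"))
    stop("only average linkage is supported")
  subset_features <- as.matrix(subset_features)
  if (nrow(subset_features) < n_neighbors)
    stop("training subset must have at least n_neighbors rows")
  hc <- stats::hclust(stats::dist(subset_features), method = "average")
  labels <- stats::cutree(hc, h = distance_threshold) - 1L
  k <- length(unique(labels))
  if (k == 1)
    warning("distance threshold yields a single cluster; ",
            "at least 3 states are recommended for pathway analysis")
  centroids <- .cluster_centroids(subset_features, labels)
  structure(list(features = subset_features, labels = as.integer(labels),
                 centroids = centroids, n_neighbors = as.integer(n_neighbors),
                 distance_threshold = distance_threshold, linkage = linkage),
            class = "two_stage_model")
}

.cluster_centroids <- function(features, labels) {
  ids <- sort(unique(labels))
  cent <- t(vapply(ids, function(l)
    colMeans(features[labels == l, , drop = FALSE]),
    numeric(ncol(features))))
  rownames(cent) <- ids
  cent
}

#' @export
print.two_stage_model <- function(x, ...) {
  cat("<two_stage_model> ", nrow(x$features), " training frames, ",
      nrow(x$centroids), " clusters (threshold ", x$distance_threshold,
      ", ", x$n_neighbors, "-NN)\n", sep = "")
  invisible(x)
}

# Deterministic kNN: Euclidean distance, neighbour ties broken by lowest
# training-row index (order() is stable), vote ties by smallest cluster id.
.knn_predict <- function(train, labels, k, query) {
  if (nrow(query) == 0) return(integer(0))
  if (ncol(query) != ncol(train)) stop("feature dimensionality mismatch")
  tn2 <- rowSums(train^2)
  out <- integer(nrow(query))
  for (i in seq_len(nrow(query))) {
    d2 <- tn2 - 2 * as.numeric(train %*% query[i, ]) + sum(query[i, ]^2)
    nb <- order(d2)[seq_len(k)]
    votes <- table(labels[nb])
    win <- names(votes)[votes == max(votes)]
    out[i] <- min(as.integer(win))
  }
  out
}

#' Predict state labels with a fitted two-stage model
#'
#' Labels every frame by majority vote of its `n_neighbors` nearest training
#' conformations (Euclidean distance; ties broken deterministically toward
#' the lowest training-row index, then the smallest cluster id).
#'
#' @param model A `two_stage_model` from [fit_two_stage()].
#' @param features Numeric matrix of frames to label (possibly empty).
#' @return Integer vector of predicted 0-based cluster labels.  The
#'   per-cluster centroids of the predicted set, used to validate the
#'   two-stage shortcut against the training clustering, are attached as
#'   attribute `"centroids"`.
#' @export
predict_two_stage <- function(model, features) {
  if (!inherits(model, "two_stage_model")) stop("model must be a two_stage_model")
  features <- as.matrix(features)
  if (nrow(features) == 0) return(structure(integer(0), centroids = NULL))
  labels <- .knn_predict(model$features, model$labels, model$n_neighbors,
                         features)
  structure(labels, centroids = .cluster_centroids(features, labels))
}

#' Assign frames with a user hook
#'
#' Runs an arbitrary assignment function over the frame batch and validates
#' its output against the declared state set.
#'
#' @param features Numeric matrix of frames.
#' @param hook Function mapping the feature matrix to one integer label per
#'   frame.
#' @param states Integer vector of valid state ids; the unassigned sentinel
#'   `-1` is always accepted.
#' @return Integer label vector.
#' @export
assign_hook <- function(features, hook, states) {
  features <- as.matrix(features)
  labels <- as.integer(hook(features))
  if (length(labels) != nrow(features))
    stop("hook-contract violation: expected ", nrow(features),
         " labels, got ", length(labels))
  bad <- setdiff(unique(labels), c(as.integer(states), UNASSIGNED))
  if (length(bad) > 0)
    stop("hook-contract violation: labels outside the declared state set: ",
         paste(bad, collapse = ", "))
  labels
}
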