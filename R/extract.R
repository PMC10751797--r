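# Extraction of successful source->target transition pathways from labelled
# trajectories.  A successful pathway runs from the last exit of the source
# state to the first entry of the target state (last-exit / first-passage
# semantics, so the event duration is the barrier-crossing time).  The
# pathway string excludes the source dwell but includes the single arrival
# symbol in the target, so at stride 1 the string length equals the event
# duration in frames.

#' Build a weighted-ensemble trajectory tree
#'
#' A simplified tabular stand-in for a weighted-ensemble data file: one row
#' per trajectory segment carrying its iteration, id, parent id, weight and
#' the per-frame state labels of that iteration.
#'
#' @param segments Data frame with integer columns `iteration` (1-based),
#'   `seg_id` (unique within an iteration), `parent_id` (`-1` for initial
#'   segments, otherwise a `seg_id` present in the previous iteration) and
#'   numeric `weight`.
#' @param labels Integer matrix, one row per segment (same order as
#'   `segments`), `tau_frames` columns of state labels.
#' @param tau_frames Frames per iteration.
#' @return An object of class `trajectory_tree`.
#' @export
trajectory_tree <- function(segments, labels, tau_frames) {
  required <- c("iteration", "seg_id", "parent_id", "weight")
  if (!all(required %in% names(segments)))
    stop("segments must have columns ", paste(required, collapse = ", "))
  labels <- as.matrix(labels)
  if (nrow(labels) != nrow(segments))
    stop("labels must have one row per segment")
  if (ncol(labels) != tau_frames)
    stop("every segment must have exactly tau_frames = ", tau_frames,
         " label entries")
  if (any(segments$weight <= 0)) stop("segment weights must be positive")
  for (it in unique(segments$iteration)) {
    rows <- segments$iteration == it
    if (anyDuplicated(segments$seg_id[rows]))
      stop("duplicate seg_id within iteration ", it)
    if (it == min(segments$iteration)) next
    parents <- segments$parent_id[rows]
    prev <- segments$seg_id[segments$iteration == it - 1]
    bad <- setdiff(parents[parents != -1L], prev)
    if (length(bad) > 0)
      stop("malformed tree: parent ", bad[1], " of iteration ", it,
           " not found in iteration ", it - 1)
  }
  sums <- tapply(segments$weight, segments$iteration, sum)
  if (any(abs(sums - 1) > 1e-6))
    warning("per-iteration weights do not sum to 1 (max deviation ",
            format(max(abs(sums - 1))), "); proceeding with given weights")
  structure(list(segments = segments, labels = labels,
                 tau_frames = as.integer(tau_frames)),
            class = "trajectory_tree")
}

#' @export
print.trajectory_tree <- function(x, ...) {
  cat("<trajectory_tree> ", nrow(x$segments), " segments over ",
      length(unique(x$segments$iteration)), " iterations (tau = ",
      x$tau_frames, " frames)\n", sep = "")
  invisible(x)
}

#' Trace the label series of a lineage
#'
#' Concatenates per-iteration label series from the root ancestor to the
#' given leaf segment, in chronological order.
#'
#' @param tree A `trajectory_tree`.
#' @param iteration,seg_id Leaf segment reference.
#' @return Integer label vector of length `iterations-in-lineage *
#'   tau_frames`.
#' @export
trace_lineage <- function(tree, iteration, seg_id) {
  seg <- tree$segments
  rows <- integer(0)
  it <- iteration; id <- seg_id
  repeat {
    r <- which(seg$iteration == it & seg$seg_id == id)
    if (length(r) != 1)
      stop("malformed tree: segment ", id, " not found at iteration ", it)
    rows <- c(r, rows)
    parent <- seg$parent_id[r]
    if (parent == -1L) break
    it <- it - 1L
    id <- parent
  }
  as.integer(t(tree$labels[rows, , drop = FALSE]))
}

# Locate transition windows (last source exit + 1 .. first target entry) in
# a label series.  Returns a matrix with columns start, end (1-based).
.transition_windows <- function(labels, source_id, target_id,
                                first_only = FALSE) {
  res <- NULL
  last_source <- NA_integer_
  for (i in seq_along(labels)) {
    s <- labels[i]
    if (s == source_id) {
      last_source <- i
    } else if (s == target_id && !is.na(last_source)) {
      res <- rbind(res, c(last_source + 1L, i))
      if (first_only) break
      last_source <- NA_integer_  # require a fresh source visit
    }
  }
  if (is.null(res)) matrix(integer(0), ncol = 2) else res
}

# Sample a window every `stride` frames, anchored at the target-entry frame
# so the arrival symbol is always retained; yields ceiling(L/stride) symbols.
.stride_indices <- function(start, end, stride) {
  rev(seq(end, start, by = -stride))
}

.window_symbols <- function(labels, start, end, stride) {
  win <- labels[.stride_indices(start, end, stride)]
  if (any(win == UNASSIGNED))
    stop("incomplete discretization: unassigned (-1) label inside a ",
         "transition (frames ", start - 1L, "..", end - 1L, ")")
  as.integer(win)
}

# Shared short-pathway alert: warn listing pathways under min_frames, and
# again when more than 25% fall below the threshold.
.short_pathway_alert <- function(paths, min_frames = 10L) {
  if (length(paths) == 0) return(invisible(NULL))
  durations <- vapply(paths, function(p) p$event_duration_frames, 0L)
  short <- which(durations < min_frames)
  if (length(short) > 0) {
    warning(length(short), " pathway(s) shorter than ", min_frames,
            " frames exist (ids: ",
            paste(utils::head(short, 10), collapse = ", "),
            if (length(short) > 10) ", ..." else "",
            "); consider --exclude-length", call. = FALSE)
    if (length(short) / length(paths) > 0.25)
      warning("more than 25% of pathways fall below the ", min_frames,
              "-frame threshold; consider a higher exclude-length",
              call. = FALSE)
  }
  invisible(short)
}

#' Extract successful pathways from a conventional-MD label series
#'
#' Scans a per-frame state-label vector for every successful source-to-target
#' transition and emits one [pathway()] per event, sampled every `stride`
#' frames (the target-arrival frame is always kept).  Weights are uniform
#' (`1/n`) over the surviving pathways.
#'
#' @param labels Integer per-frame state labels (the unassigned sentinel `-1`
#'   may appear outside transitions only).
#' @param source_id,target_id State ids delimiting a successful event.
#' @param stride Keep every `stride`-th frame (>= 1); coarser time
#'   resolution shortens strings proportionally.
#' @param exclude_length Drop pathways with fewer than this many symbols
#'   (0 keeps everything).
#' @return List of `pathway` objects.  Warns when pathways shorter than 10
#'   frames exist, and again when they exceed 25% of the ensemble.
#' @examples
#' labs <- c(0, 0, 2, 3, 1, 0, 2, 1) # 0 = source, 1 = target
#' extract_cmd(labs, 0, 1)           # two pathways: "231" and "21"
#' @export
extract_cmd <- function(labels, source_id, target_id, stride = 1L,
                        exclude_length = 0L) {
  if (stride < 1) stop("stride must be >= 1")
  if (exclude_length < 0) stop("exclude_length must be >= 0")
  labels <- as.integer(labels)
  win <- .transition_windows(labels, source_id, target_id)
  paths <- list()
  for (r in seq_len(nrow(win))) {
    symbols <- .window_symbols(labels, win[r, 1], win[r, 2], stride)
    paths[[length(paths) + 1]] <- pathway(
      symbols,
      weight = NA,
      start_frame = win[r, 1] - 1L, end_frame = win[r, 2] - 1L,
      event_duration_frames = win[r, 2] - win[r, 1] + 1L,
      origin = list(kind = "cmd", trajectory = 1L), id = r)
  }
  paths <- Filter(function(p) length(p$symbols) >= exclude_length, paths)
  n <- length(paths)
  for (i in seq_len(n)) { paths[[i]]$weight <- 1 / n; paths[[i]]$id <- i }
  .short_pathway_alert(paths)
  paths
}

#' Extract pathways from an ensemble of independent trajectories
#'
#' Runs the [extract_cmd()] scan over each label series in a list (e.g. one
#' per independent simulation), pools the resulting pathways, reassigns
#' uniform weights over the pooled set, and raises the short-pathway alerts
#' once for the whole ensemble.
#'
#' @param labels_list List of per-frame state-label vectors.
#' @inheritParams extract_cmd
#' @return List of `pathway` objects with `origin$trajectory` identifying
#'   the source series.
#' @export
extract_ensemble <- function(labels_list, source_id, target_id, stride = 1L,
                             exclude_length = 0L) {
  paths <- list()
  for (t in seq_along(labels_list)) {
    pp <- suppressWarnings(
      extract_cmd(labels_list[[t]], source_id, target_id, stride = stride,
                  exclude_length = exclude_length))
    for (p in pp) {
      p$origin$trajectory <- t
      paths[[length(paths) + 1]] <- p
    }
  }
  n <- length(paths)
  for (i in seq_len(n)) { paths[[i]]$weight <- 1 / n; paths[[i]]$id <- i }
  .short_pathway_alert(paths)
  paths
}

#' Extract successful pathways from a weighted-ensemble trajectory tree
#'
#' For every segment in whose own frames a target entry occurs, traces the
#' lineage back to the root, locates the last source exit before that entry,
#' and emits one [pathway()] weighted by the arriving segment's weight at
#' the arrival iteration.  History sharing between arriving segments is
#' allowed (each arrival is one pathway), and lineages recycled through the
#' source can arrive more than once.  Segments reaching the target with no
#' preceding source visit anywhere in their lineage are skipped with a
#' message.
#'
#' @param tree A [trajectory_tree()].
#' @param source_id,target_id State ids delimiting a successful event.
#' @param stride Keep every `stride`-th frame; must divide `tau_frames`.
#'   `stride = 1` uses every saved frame; `stride = tau_frames` reproduces
#'   the one-symbol-per-iteration default.  If the transition starts or ends
#'   inside an iteration, only the sub-interval frames after the source exit
#'   and before the target entry are considered.
#' @param exclude_length Drop pathways with fewer than this many symbols.
#' @return List of `pathway` objects with weighted-ensemble weights.
#' @export
extract_we <- function(tree, source_id, target_id, stride = 1L,
                       exclude_length = 0L) {
  if (!inherits(tree, "trajectory_tree")) stop("tree must be a trajectory_tree")
  if (stride < 1) stop("stride must be >= 1")
  if (tree$tau_frames %% stride != 0)
    stop("stride must divide tau_frames (", tree$tau_frames, ")")
  seg <- tree$segments
  paths <- list()
  for (r in seq_len(nrow(seg))) {
    own <- tree$labels[r, ]
    if (!any(own == target_id)) next
    series <- trace_lineage(tree, seg$iteration[r], seg$seg_id[r])
    seg_start <- length(series) - tree$tau_frames + 1L
    first_target <- which(series == target_id)[1]
    if (first_target >= seg_start &&
        !any(series[seq_len(first_target - 1L)] == source_id)) {
      message("segment ", seg$seg_id[r], " at iteration ", seg$iteration[r],
              " reaches the target without a preceding source visit; skipped")
    }
    # a segment is an arrival for every transition whose target entry falls
    # within its own frames (recycled lineages can arrive more than once)
    win <- .transition_windows(series, source_id, target_id)
    win <- win[win[, 2] >= seg_start, , drop = FALSE]
    for (w in seq_len(nrow(win))) {
      symbols <- .window_symbols(series, win[w, 1], win[w, 2], stride)
      paths[[length(paths) + 1]] <- pathway(
        symbols,
        weight = seg$weight[r],
        start_frame = win[w, 1] - 1L, end_frame = win[w, 2] - 1L,
        event_duration_frames = win[w, 2] - win[w, 1] + 1L,
        origin = list(kind = "we", iteration = seg$iteration[r],
                      seg_id = seg$seg_id[r]),
        id = length(paths) + 1)
    }
  }
  paths <- Filter(function(p) length(p$symbols) >= exclude_length, paths)
  for (i in seq_along(paths)) paths[[i]]$id <- i
  .short_pathway_alert(paths)
  paths
}
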