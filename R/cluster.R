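# Ward-linkage clustering of the pathway distance matrix and class-level
# summaries.  Note the 1 - similarity distances are not a Euclidean
# embedding; Ward linkage is applied to them directly (Lance-Williams
# update on the precomputed distances), so merge heights are ordinal rather
# than geometric quantities.

#' Ward-linkage hierarchical clustering of a pathway distance matrix
#'
#' @param d Symmetric distance matrix with zero diagonal (from
#'   [pairwise_distances()]), or a `dist` object.
#' @return An object of class `linkage_tree`: the merge table (`merges`,
#'   with columns `a`, `b`, `height`, `size`; negative entries denote
#'   leaves, positive entries earlier merges, as in [stats::hclust()]),
#'   `n_leaves`, and the underlying `hclust` object.
#' @export
ward_linkage <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(n) || n < 2) stop("too few pathways: need at least 2")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)) ||
      any(abs(diag(d)) > 1e-12))
    stop("d must be symmetric with a zero diagonal")
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  sizes <- integer(n - 1)
  for (m in seq_len(n - 1)) {
    count <- function(x) if (x < 0) 1L else sizes[x]
    sizes[m] <- count(hc$merge[m, 1]) + count(hc$merge[m, 2])
  }
  merges <- data.frame(a = hc$merge[, 1], b = hc$merge[, 2],
                       height = hc$height, size = sizes)
  structure(list(merges = merges, n_leaves = n, hclust = hc),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat("<linkage_tree> ", x$n_leaves, " pathways, max merge height ",
      format(max(x$merges$height), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Suggest a dendrogram cut at the largest height gap
#'
#' Places a horizontal cut at the midpoint of the largest gap between
#' consecutive merge heights, the point dividing the dendrogram between
#' nodes with maximum distance separation.  All merges participate in the
#' gap search; ties are broken toward fewer classes (cutting too low tends
#' to produce classes with redundant features).  The cut is a suggestion:
#' pass your own `cut_height` to [assign_classes()] to explore alternatives.
#'
#' @param tree A `linkage_tree` from [ward_linkage()].
#' @return List with `cut_height` and `n_classes`.  When all merge heights
#'   are equal the dendrogram carries no class structure: one class is
#'   returned with a degeneracy warning.
#' @export
suggest_cut <- function(tree) {
  if (!inherits(tree, "linkage_tree")) stop("tree must be a linkage_tree")
  h <- sort(tree$merges$height)
  n <- tree$n_leaves
  if (length(h) == 1) { # two leaves: one merge, cut below it if non-trivial
    if (h > 0) return(list(cut_height = h / 2, n_classes = 2L))
    warning("degenerate dendrogram: all merge heights equal; one class")
    return(list(cut_height = h + 1, n_classes = 1L))
  }
  if (max(h) - min(h) < .Machine$double.eps^0.5) {
    warning("degenerate dendrogram: all merge heights equal; one class")
    return(list(cut_height = max(h) + 1, n_classes = 1L))
  }
  gaps <- diff(h)
  best <- max(gaps)
  # ties toward fewer classes = the highest qualifying gap
  g <- max(which(gaps >= best - .Machine$double.eps^0.5 * max(1, best)))
  cut_height <- (h[g] + h[g + 1]) / 2
  list(cut_height = cut_height, n_classes = as.integer(n - g))
}

#' Assign pathway classes by cutting the dendrogram
#'
#' Connected components below `cut_height` become the classes, numbered
#' `1..k` by decreasing total pathway weight (so class 1 is always the most
#' probable route).
#'
#' @param tree A `linkage_tree`.
#' @param cut_height Height of the horizontal cut.
#' @param weights Optional per-pathway weights used to order the class
#'   labels; equal weights assumed when omitted.
#' @return Integer vector of class labels, one per pathway.
#' @export
assign_classes <- function(tree, cut_height, weights = NULL) {
  if (!inherits(tree, "linkage_tree")) stop("tree must be a linkage_tree")
  raw <- stats::cutree(tree$hclust, h = cut_height)
  if (is.null(weights)) weights <- rep(1, tree$n_leaves)
  totals <- tapply(weights, raw, sum)
  ord <- order(-totals, as.integer(names(totals)))
  relabel <- integer(length(totals))
  relabel[as.integer(names(totals))[ord]] <- seq_along(ord)
  as.integer(relabel[raw])
}

#' Class probabilities from pathway weights
#'
#' @param pathways List of `pathway` objects (or anything; only weights are
#'   used, defaulting to 1).
#' @param class_of Integer class label per pathway.
#' @return Named numeric vector of per-class summed weight fractions
#'   (sums to 1).
#' @export
class_probabilities <- function(pathways, class_of) {
  w <- vapply(pathways, pathway_weight, 0)
  total <- sum(w)
  if (total <= 0) stop("zero total pathway weight")
  p <- tapply(w, class_of, sum) / total
  out <- as.numeric(p)
  names(out) <- names(p)
  out[order(as.integer(names(out)))]
}

#' Event-duration lists per pathway class
#'
#' @inheritParams class_probabilities
#' @param frame_interval Optional physical time per frame; when given, a
#'   `"time"` attribute with durations in physical units is attached to each
#'   class's vector.
#' @return Named list mapping class label to the integer vector of event
#'   durations (frames) of its pathways; full lists, no truncation.
#' @export
duration_histograms <- function(pathways, class_of, frame_interval = NULL) {
  durs <- vapply(pathways, function(p)
    if (inherits(p, "pathway")) p$event_duration_frames
    else length(as_symbols(p)), 0L)
  out <- split(durs, class_of)
  if (!is.null(frame_interval))
    out <- lapply(out, function(v) structure(v, time = v * frame_interval))
  out
}

#' Directed state-transition network per pathway class
#'
#' Condenses each pathway string and accumulates the directed edges
#' `s_i -> s_(i+1)` with weights equal to the summed pathway weights
#' traversing the edge; per-state node weights (summed weights of pathways
#' visiting the state) are attached as attribute `"nodes"`.  Edges are
#' reported per class and pooled over all pathways (class `"all"`).
#'
#' @inheritParams class_probabilities
#' @param condense_level Condensation level applied before edge counting
#'   (default 2, the fundamental-route level); 0 disables.
#' @return Data frame with columns `class`, `from`, `to`, `weight`.
#' @export
network_edges <- function(pathways, class_of = NULL, condense_level = 2) {
  if (length(pathways) == 0)
    return(data.frame(class = character(0), from = integer(0),
                      to = integer(0), weight = numeric(0)))
  if (is.null(class_of)) class_of <- rep(1L, length(pathways))
  syms <- lapply(pathways, as_symbols)
  if (!is.null(condense_level) && condense_level >= 1)
    syms <- lapply(syms, condense, max_block = condense_level)
  w <- vapply(pathways, pathway_weight, 0)
  groups <- c(list(all = seq_along(pathways)),
              split(seq_along(pathways), class_of))
  rows <- list(); nodes <- list()
  for (g in names(groups)) {
    acc <- new.env(parent = emptyenv())
    nacc <- new.env(parent = emptyenv())
    for (i in groups[[g]]) {
      s <- syms[[i]]
      for (st in unique(s)) {
        key <- as.character(st)
        nacc[[key]] <- (if (is.null(nacc[[key]])) 0 else nacc[[key]]) + w[i]
      }
      if (length(s) < 2) next
      for (j in seq_len(length(s) - 1)) {
        key <- paste(s[j], s[j + 1], sep = ">")
        acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + w[i]
      }
    }
    for (key in ls(acc)) {
      ft <- as.integer(strsplit(key, ">", fixed = TRUE)[[1]])
      rows[[length(rows) + 1]] <- data.frame(class = g, from = ft[1],
                                             to = ft[2], weight = acc[[key]])
    }
    for (key in ls(nacc))
      nodes[[length(nodes) + 1]] <- data.frame(class = g,
                                               state = as.integer(key),
                                               weight = nacc[[key]])
  }
  edges <- do.call(rbind, rows)
  edges <- edges[order(edges$class, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- do.call(rbind, nodes)
  nodes <- nodes[order(nodes$class, nodes$state), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(edges, nodes = nodes)
}

#' Full pathway classification report
#'
#' Convenience wrapper running the complete matching stage: distance matrix,
#' Ward linkage, (suggested or user-supplied) dendrogram cut, class labels,
#' class probabilities, duration lists and the directed network.  Emits the
#' workflow guardrail warnings: fewer than 3 discrete states, fewer than 50
#' pathways, or any class with fewer than 10 members makes the statistics
#' fragile.
#'
#' @param pathways List of `pathway` objects.
#' @param corrected,condense_level,metric_hook,method Passed to
#'   [pairwise_distances()].
#' @param cut_height Optional dendrogram cut; defaults to the
#'   [suggest_cut()] max-gap cut.
#' @param n_classes Optional class-count override (takes precedence over
#'   `cut_height`).
#' @param frame_interval Optional physical time per frame for durations.
#' @return An object of class `class_report` with fields `class_of`,
#'   `class_prob`, `durations`, `edges`, `cut_height`, `n_classes`,
#'   `distance_matrix` and `linkage`.
#' @export
class_report <- function(pathways, corrected = TRUE, condense_level = 2,
                         metric_hook = NULL, method = "lcs",
                         cut_height = NULL, n_classes = NULL,
                         frame_interval = NULL) {
  n <- length(pathways)
  if (n < 50)
    warning("fewer than 50 pathways (", n,
            "); class statistics may not be robust", call. = FALSE)
  n_states <- length(unique(unlist(lapply(pathways, as_symbols))))
  if (n_states < 3)
    warning("fewer than 3 discrete states (", n_states,
            "); consider refining the discretization", call. = FALSE)
  d <- pairwise_distances(pathways, corrected = corrected,
                          condense_level = condense_level,
                          metric_hook = metric_hook, method = method)
  tree <- ward_linkage(d)
  if (!is.null(n_classes)) {
    raw <- stats::cutree(tree$hclust, k = n_classes)
    h <- sort(tree$merges$height)
    cut_height <- if (n_classes >= n) 0 else
      mean(h[c(n - n_classes, min(n - n_classes + 1, length(h)))])
  } else if (is.null(cut_height)) {
    cut <- suggest_cut(tree)
    cut_height <- cut$cut_height
  }
  w <- vapply(pathways, pathway_weight, 0)
  class_of <- assign_classes(tree, cut_height, weights = w)
  sizes <- table(class_of)
  if (any(sizes < 10))
    warning("class(es) with fewer than 10 pathways: ",
            paste(names(sizes)[sizes < 10], collapse = ", "), call. = FALSE)
  structure(list(
    class_of = class_of,
    class_prob = class_probabilities(pathways, class_of),
    durations = duration_histograms(pathways, class_of, frame_interval),
    edges = network_edges(pathways, class_of, condense_level),
    cut_height = cut_height,
    n_classes = length(unique(class_of)),
    distance_matrix = d,
    linkage = tree), class = "class_report")
}

#' @export
print.class_report <- function(x, ...) {
  cat("<class_report> ", length(x$class_of), " pathways in ", x$n_classes,
      " class(es), cut at ", format(x$cut_height, digits = 4), "\n", sep = "")
  for (cl in names(x$class_prob))
    cat(sprintf("  class %s: %d pathways, probability %.3f\n", cl,
                sum(x$class_of == as.integer(cl)), x$class_prob[[cl]]))
  invisible(x)
}
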