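# Independent oracles used to cross-check the implementation.  Each is a
# deliberately naive second implementation kept separate from the package
# code paths it verifies.

# Is `sub` a (not necessarily contiguous) subsequence of `x`?
is_subsequence <- function(sub, x) {
  if (length(sub) == 0) return(TRUE)
  j <- 1
  for (i in seq_along(x)) {
    if (x[i] == sub[j]) {
      j <- j + 1
      if (j > length(sub)) return(TRUE)
    }
  }
  FALSE
}

# Brute-force LCS by enumerating subsequences of the shorter string, longest
# first, and testing containment in the other string.
oracle_lcs <- function(a, b) {
  if (length(b) < length(a)) { tmp <- a; a <- b; b <- tmp }
  n <- length(a)
  if (n == 0) return(0L)
  masks <- 0:(2^n - 1)
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:(n - 1))) > 0), 0)
  for (m in masks[order(-sizes)]) {
    sub <- a[bitwAnd(m, 2^(0:(n - 1))) > 0]
    if (is_subsequence(sub, b)) return(length(sub))
  }
  0L
}

# Brute-force Ward agglomeration (Lance-Williams update on the given
# distances, squared form, heights reported on the distance scale).
oracle_ward_heights <- function(d) {
  n <- nrow(d)
  d2 <- d^2
  active <- seq_len(n)
  sizes <- rep(1, n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bestv <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      v <- d2[active[ii], active[jj]]
      if (v < bestv) { bestv <- v; best <- c(ii, jj) }
    }
    i <- active[best[1]]; j <- active[best[2]]
    heights <- c(heights, sqrt(bestv))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- sizes[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * bestv) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# Recursive lineage walk, independent of trace_lineage()'s iterative code.
oracle_trace <- function(tree, iteration, seg_id) {
  r <- which(tree$segments$iteration == iteration &
               tree$segments$seg_id == seg_id)
  stopifnot(length(r) == 1)
  own <- as.integer(tree$labels[r, ])
  parent <- tree$segments$parent_id[r]
  if (parent == -1L) return(own)
  c(oracle_trace(tree, iteration - 1L, parent), own)
}

# Random state-id vector over an alphabet of k symbols.
random_symbols <- function(len, k = 4) sample.int(k, len, replace = TRUE) - 1L

# Best-case agreement between a 2-class partition and 2-route ground truth.
two_class_agreement <- function(classes, routes) {
  max(mean((classes == 1) == (routes == 1)),
      mean((classes == 1) == (routes == 2)))
}

# Majority-mapping accuracy of predicted cluster labels vs generating labels.
majority_accuracy <- function(pred, truth) {
  correct <- 0
  for (cl in unique(pred)) {
    sel <- pred == cl
    correct <- correct + max(table(truth[sel]))
  }
  correct / length(truth)
}

# Default synthetic two-route generation + extraction used in several tests.
make_two_route_paths <- function(seed, n_paths = 80) {
  ens <- generate_pathway_ensemble(default_route_spec(), n_paths, seed = seed)
  paths <- suppressWarnings(extract_ensemble(ens$labels, 0, 5))
  list(paths = paths, routes = ens$route)
}

# Symbol accessor for path_string/pathway objects without touching package
# internals.
as_symbols_test <- function(p) {
  if (inherits(p, "pathway")) p$symbols else decode_symbols(as.character(p))
}
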