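# Seeded synthetic fixtures: a discrete-state two-route Markov pathway
# ensemble (a minimal analogue of a conformational transition with an upper
# and a lower route over the barrier), Gaussian "conformation" clouds in a
# periodic 2-D angle space for discretization tests, and small
# weighted-ensemble trajectory trees with conserved weights.

#' Specify a synthetic multi-route transition ensemble
#'
#' Describes a Markovian state-hopping world: a source state, a target
#' state, and a set of routes between them, each traversed with geometric
#' dwell times and occasional single-frame excursions to off-route states.
#'
#' @param states Integer vector of all state ids.
#' @param source,target Source and target state ids.
#' @param routes List of `list(seq =, prob =)`: a state sequence from source
#'   to target and its probability.  Probabilities must sum to 1.
#' @param dwell_mean Mean frames spent per visited state (geometric dwell,
#'   >= 1).
#' @param noise_rate Per-frame probability of a one-frame excursion to a
#'   random off-route intermediate state.
#' @return An object of class `route_spec`.
#' @export
route_spec <- function(states, source, target, routes, dwell_mean = 3,
                       noise_rate = 0.05) {
  probs <- vapply(routes, function(r) r$prob, 0)
  if (abs(sum(probs) - 1) > 1e-9) stop("route probabilities must sum to 1")
  if (dwell_mean < 1) stop("dwell_mean must be >= 1")
  if (noise_rate < 0 || noise_rate >= 1) stop("noise_rate must be in [0, 1)")
  for (r in routes) {
    if (r$seq[1] != source || r$seq[length(r$seq)] != target)
      stop("every route must start at the source and end at the target")
    if (!all(r$seq %in% states)) stop("route visits an undeclared state")
  }
  if (source == target) stop("source and target must differ")
  structure(list(states = as.integer(states), source = as.integer(source),
                 target = as.integer(target), routes = routes,
                 dwell_mean = dwell_mean, noise_rate = noise_rate),
            class = "route_spec")
}

#' Default two-route benchmark specification
#'
#' Six states with a source (0) and target (5) joined by an upper route
#' `0-3-4-5` (probability 0.875) and a lower route `0-1-2-5` (probability
#' 0.125), the scale of a typical small-peptide conformational-transition
#' benchmark.
#'
#' @param dwell_mean,noise_rate See [route_spec()].
#' @return A `route_spec`.
#' @export
default_route_spec <- function(dwell_mean = 3, noise_rate = 0.05) {
  route_spec(states = 0:5, source = 0L, target = 5L,
             routes = list(list(seq = c(0L, 3L, 4L, 5L), prob = 0.875),
                           list(seq = c(0L, 1L, 2L, 5L), prob = 0.125)),
             dwell_mean = dwell_mean, noise_rate = noise_rate)
}

# Off-route intermediate states available for noise excursions.
.offroute_states <- function(spec, route_seq) {
  setdiff(spec$states, c(route_seq, spec$source, spec$target))
}

# One trajectory: source dwell, route traversal with geometric dwells and
# noise excursions, single target arrival frame.
.simulate_trajectory <- function(spec, route_idx) {
  p_leave <- 1 / spec$dwell_mean
  route <- spec$routes[[route_idx]]$seq
  off <- .offroute_states(spec, route)
  labs <- integer(0)
  for (pos in seq_len(length(route) - 1L)) {
    st <- route[pos]
    dwell <- stats::rgeom(1, p_leave) + 1L
    for (f in seq_len(dwell)) {
      labs <- c(labs, st)
      if (length(off) > 0 && stats::runif(1) < spec$noise_rate)
        labs <- c(labs, sample(off, 1))
    }
  }
  c(labs, spec$target)
}

#' Generate a labelled pathway ensemble with ground truth
#'
#' Simulates `n_paths` independent trajectories from the source to the
#' target: each samples a route by its probability, dwells geometrically in
#' every on-route state, occasionally takes one-frame excursions to
#' off-route states, and stops at first target entry.
#'
#' @param spec A [route_spec()].
#' @param n_paths Number of trajectories (>= 1).
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return List with `labels` (list of per-frame state-label vectors, each
#'   starting with the source dwell and ending at the target), `route`
#'   (ground-truth route index per trajectory) and `weights` (uniform,
#'   summing to 1).
#' @export
generate_pathway_ensemble <- function(spec, n_paths = 80L, seed = 1L) {
  if (!inherits(spec, "route_spec")) stop("spec must be a route_spec")
  if (n_paths < 1) stop("n_paths must be >= 1")
  old <- .GlobalEnv$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)
  probs <- vapply(spec$routes, function(r) r$prob, 0)
  route <- sample.int(length(spec$routes), n_paths, replace = TRUE,
                      prob = probs)
  labels <- lapply(route, function(ri) .simulate_trajectory(spec, ri))
  list(labels = labels, route = route,
       weights = rep(1 / n_paths, n_paths))
}

#' Generate isotropic Gaussian conformation clouds
#'
#' Samples `n_per` points around each centroid with standard deviation
#' `sigma` per coordinate, emulating clusters of conformations in a
#' (periodicity-remapped) torsion-angle plane.
#'
#' @param centroids Numeric matrix, one centroid per row.
#' @param sigma Isotropic standard deviation (0 gives exact centroids).
#' @param n_per Points per centroid.
#' @param seed Integer seed.
#' @return List with `features` (matrix) and 0-based generating `labels`.
#' @export
generate_blobs <- function(centroids, sigma, n_per, seed = 1L) {
  centroids <- as.matrix(centroids)
  if (anyDuplicated(centroids) > 0) stop("centroids must be distinct")
  old <- .GlobalEnv$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)
  k <- nrow(centroids); d <- ncol(centroids)
  features <- matrix(NA_real_, k * n_per, d)
  labels <- integer(k * n_per)
  for (i in seq_len(k)) {
    rows <- ((i - 1) * n_per + 1):(i * n_per)
    features[rows, ] <- matrix(stats::rnorm(n_per * d, sd = sigma),
                               n_per, d) +
      matrix(centroids[i, ], n_per, d, byrow = TRUE)
    labels[rows] <- i - 1L
  }
  list(features = features, labels = labels)
}

#' Generate a small weighted-ensemble trajectory tree
#'
#' Runs `segs_per_iteration` walkers of Markovian route dynamics for
#' `n_iterations` resampling intervals of `tau_frames` frames each.  Between
#' iterations the heaviest walker is split into two half-weight children and
#' the two lightest walkers are merged (the surviving child continues the
#' heavier parent's dynamics), so the per-iteration weights always sum to
#' exactly 1 and the segment table forms a genuine split/merge tree.  With a
#' single walker the tree degenerates to a flat chain identical to a
#' conventional-MD label series.
#'
#' @param spec A [route_spec()] driving the per-frame state dynamics (the
#'   target is absorbing).
#' @param n_iterations,segs_per_iteration,tau_frames Positive tree
#'   dimensions.
#' @param seed Integer seed.
#' @return A [trajectory_tree()].
#' @export
generate_we_tree <- function(spec, n_iterations = 20L,
                             segs_per_iteration = 4L, tau_frames = 5L,
                             seed = 1L) {
  if (!inherits(spec, "route_spec")) stop("spec must be a route_spec")
  if (n_iterations < 1 || segs_per_iteration < 1 || tau_frames < 1)
    stop("tree dimensions must be positive")
  old <- .GlobalEnv$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)
  p_leave <- 1 / spec$dwell_mean
  probs <- vapply(spec$routes, function(r) r$prob, 0)

  # per-walker dynamic state: current label, committed route, position on it,
  # pending return state after a noise excursion
  new_walker <- function() list(label = spec$source, route = NA_integer_,
                                pos = 1L, ret = NA_integer_)
  step <- function(w) {
    if (w$label == spec$target) return(w)           # absorbing
    if (!is.na(w$ret)) { w$label <- w$ret; w$ret <- NA_integer_; return(w) }
    if (stats::runif(1) < p_leave) {
      if (w$label == spec$source || is.na(w$route)) {
        w$route <- sample.int(length(spec$routes), 1, prob = probs)
        w$pos <- 2L
      } else {
        w$pos <- w$pos + 1L
      }
      w$label <- spec$routes[[w$route]]$seq[w$pos]
    } else {
      off <- .offroute_states(spec, spec$routes[[if (is.na(w$route)) 1 else w$route]]$seq)
      if (length(off) > 0 && stats::runif(1) < spec$noise_rate) {
        w$ret <- w$label
        w$label <- sample(off, 1)
      }
    }
    w
  }

  walkers <- replicate(segs_per_iteration, new_walker(), simplify = FALSE)
  weights <- rep(1 / segs_per_iteration, segs_per_iteration)
  parents <- rep(-1L, segs_per_iteration)
  seg_rows <- list(); label_rows <- list()
  for (it in seq_len(n_iterations)) {
    labmat <- matrix(NA_integer_, length(walkers), tau_frames)
    for (s in seq_along(walkers)) {
      for (f in seq_len(tau_frames)) {
        labmat[s, f] <- walkers[[s]]$label
        walkers[[s]] <- step(walkers[[s]])
      }
    }
    seg_rows[[it]] <- data.frame(iteration = it,
                                 seg_id = seq_along(walkers) - 1L,
                                 parent_id = parents, weight = weights)
    label_rows[[it]] <- labmat
    if (it == n_iterations) break
    # resample: split heaviest, merge the two lightest (deterministic ties)
    if (length(walkers) >= 3) {
      hi <- which.max(weights)
      lo <- utils::head(setdiff(order(weights), hi), 2)
      keep <- lo[which.max(weights[lo])]   # survivor continues heavier parent
      next_walkers <- list(); next_weights <- c(); next_parents <- c()
      for (s in seq_along(walkers)) {
        if (s == hi) {
          for (cc in 1:2) {
            next_walkers <- c(next_walkers, list(walkers[[s]]))
            next_weights <- c(next_weights, weights[s] / 2)
            next_parents <- c(next_parents, s - 1L)
          }
        } else if (s %in% lo) {
          if (s == keep) {
            next_walkers <- c(next_walkers, list(walkers[[s]]))
            next_weights <- c(next_weights, sum(weights[lo]))
            next_parents <- c(next_parents, s - 1L)
          } # the lighter merged walker terminates
        } else {
          next_walkers <- c(next_walkers, list(walkers[[s]]))
          next_weights <- c(next_weights, weights[s])
          next_parents <- c(next_parents, s - 1L)
        }
      }
      walkers <- next_walkers; weights <- next_weights
      parents <- as.integer(next_parents)
    } else {
      parents <- seq_along(walkers) - 1L
    }
  }
  segments <- do.call(rbind, seg_rows)
  labels <- do.call(rbind, label_rows)
  trajectory_tree(segments, labels, tau_frames)
}
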