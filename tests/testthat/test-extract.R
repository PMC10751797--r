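# Label conventions in these fixtures: 0 = source, 9 = target unless noted.

test_that("extract_cmd finds every source-exit/target-entry window", {
  labs <- c(0, 0, 1, 2, 9, 0, 1, 9)  # S S A B T S A T
  paths <- suppressWarnings(extract_cmd(labs, 0, 9))
  expect_length(paths, 2)
  expect_identical(paths[[1]]$symbols, c(1L, 2L, 9L))
  expect_identical(paths[[2]]$symbols, c(1L, 9L))
  expect_identical(paths[[1]]$start_frame, 2L)  # 0-based
  expect_identical(paths[[1]]$end_frame, 4L)
  expect_identical(paths[[1]]$event_duration_frames, 3L)
  expect_equal(vapply(paths, function(p) p$weight, 0), c(0.5, 0.5))
})

test_that("no transition yields an empty list and filters are monotone", {
  expect_length(extract_cmd(rep(0L, 10), 0, 9), 0)
  labs <- c(0, 0, 1, 2, 9, 0, 1, 9)
  kept <- suppressWarnings(extract_cmd(labs, 0, 9, exclude_length = 3))
  expect_length(kept, 1)
  expect_identical(kept[[1]]$symbols, c(1L, 2L, 9L))
  expect_equal(kept[[1]]$weight, 1)  # weights re-uniformed after filtering
  for (xl in 0:5) {
    n_xl <- length(suppressWarnings(extract_cmd(labs, 0, 9,
                                                exclude_length = xl)))
    n_next <- length(suppressWarnings(extract_cmd(labs, 0, 9,
                                                  exclude_length = xl + 1)))
    expect_gte(n_xl, n_next)
  }
})

test_that("source re-entry restarts the clock; recrossings are ignored", {
  # source exit, wander, back to source, then the real crossing
  labs <- c(0, 1, 2, 0, 3, 9, 3, 9)
  paths <- suppressWarnings(extract_cmd(labs, 0, 9))
  expect_length(paths, 1)                       # recross 9 at end ignored
  expect_identical(paths[[1]]$symbols, c(3L, 9L))  # last-exit semantics
})

test_that("stride subsamples windows keeping the arrival symbol", {
  labs <- c(0L, rep(c(1L, 2L, 3L), 7), 9L)  # 21-frame transition + target
  p1 <- suppressWarnings(extract_cmd(labs, 0, 9, stride = 1))[[1]]
  L <- length(p1$symbols)
  for (s in c(2L, 3L, 5L, 10L)) {
    ps <- suppressWarnings(extract_cmd(labs, 0, 9, stride = s))[[1]]
    expect_identical(length(ps$symbols), as.integer(ceiling(L / s)))
    expect_identical(ps$symbols[length(ps$symbols)], 9L)
    expect_identical(ps$event_duration_frames, p1$event_duration_frames)
  }
  expect_error(extract_cmd(labs, 0, 9, stride = 0), "stride")
})

test_that("unassigned labels inside a transition are an error", {
  expect_error(suppressWarnings(extract_cmd(c(0, 1, -1, 9), 0, 9)),
               "incomplete discretization")
  # unassigned outside any transition is tolerated
  expect_length(suppressWarnings(extract_cmd(c(-1, 0, 1, 9, -1), 0, 9)), 1)
})

test_that("short-pathway alerts fire as specified", {
  w <- capture_warnings(extract_cmd(c(0, 1, 9), 0, 9))
  expect_true(any(grepl("shorter than 10 frames", w)))
  expect_true(any(grepl("more than 25%", w)))
  long <- c(0, rep(1, 20), 9)
  expect_silent(extract_cmd(long, 0, 9))
})

test_that("emitted windows contain no interior source/target symbols", {
  set.seed(21)
  for (i in 1:25) {
    labs <- sample(c(0L, 1L, 2L, 3L, 9L), 60, replace = TRUE)
    paths <- suppressWarnings(extract_cmd(labs, 0, 9))
    for (p in paths) {
      inner <- p$symbols[-length(p$symbols)]
      expect_false(any(inner == 0L) || any(inner == 9L))
      expect_identical(p$symbols[length(p$symbols)], 9L)
    }
    w <- vapply(paths, function(p) p$weight, 0)
    if (length(w) > 0) expect_equal(sum(w), 1)
  }
})

make_chain_tree <- function(labmat, weights = NULL) {
  n <- nrow(labmat)
  trajectory_tree(
    data.frame(iteration = seq_len(n), seg_id = 0L,
               parent_id = c(-1L, rep(0L, n - 1)),
               weight = if (is.null(weights)) rep(1, n) else weights),
    labmat, tau_frames = ncol(labmat))
}

test_that("trace_lineage walks chains and validates links", {
  tree <- make_chain_tree(rbind(c(0L, 0L), c(1L, 2L), c(3L, 9L)))
  expect_identical(trace_lineage(tree, 3L, 0L), c(0L, 0L, 1L, 2L, 3L, 9L))
  expect_identical(trace_lineage(tree, 1L, 0L), c(0L, 0L))
  expect_error(trace_lineage(tree, 3L, 7L), "not found")
})

test_that("trace_lineage matches an independent recursive walk", {
  spec <- default_route_spec()
  tree <- generate_we_tree(spec, n_iterations = 12, segs_per_iteration = 4,
                           tau_frames = 5, seed = 31)
  seg <- tree$segments
  for (r in which(seg$iteration == max(seg$iteration))) {
    expect_identical(trace_lineage(tree, seg$iteration[r], seg$seg_id[r]),
                     oracle_trace(tree, seg$iteration[r], seg$seg_id[r]))
  }
})

test_that("extract_we equals extract_cmd on a single-lineage tree", {
  labs <- c(0L, 0L, 1L, 2L, 9L, 0L, 1L, 9L, 9L, 9L)
  tree <- make_chain_tree(matrix(labs, nrow = 5, byrow = TRUE))
  we <- suppressWarnings(extract_we(tree, 0, 9))
  cmd <- suppressWarnings(extract_cmd(labs, 0, 9))
  expect_length(we, length(cmd))
  for (i in seq_along(cmd)) {
    expect_identical(we[[i]]$symbols, cmd[[i]]$symbols)
    expect_identical(we[[i]]$start_frame, cmd[[i]]$start_frame)
    expect_identical(we[[i]]$event_duration_frames,
                     cmd[[i]]$event_duration_frames)
    expect_equal(we[[i]]$weight, 1)  # chain weight at arrival iteration
  }
})

test_that("shared history yields pathways with a common prefix", {
  segments <- data.frame(
    iteration = c(1L, 2L, 2L),
    seg_id = c(0L, 0L, 1L),
    parent_id = c(-1L, 0L, 0L),
    weight = c(1, 0.5, 0.5))
  labels <- rbind(c(0L, 1L, 2L), c(3L, 9L, 9L), c(2L, 3L, 9L))
  tree <- trajectory_tree(segments, labels, tau_frames = 3)
  paths <- suppressWarnings(extract_we(tree, 0, 9))
  expect_length(paths, 2)
  strs <- lapply(paths, function(p) p$symbols)
  expect_identical(strs[[1]], c(1L, 2L, 3L, 9L))
  expect_identical(strs[[2]], c(1L, 2L, 2L, 3L, 9L))
  expect_equal(vapply(paths, function(p) p$weight, 0), c(0.5, 0.5))
})

test_that("stride = tau_frames shortens strings by the tau ratio", {
  spec <- default_route_spec(dwell_mean = 8, noise_rate = 0)
  tree <- generate_we_tree(spec, n_iterations = 40, segs_per_iteration = 1,
                           tau_frames = 10, seed = 12)
  fine <- suppressWarnings(extract_we(tree, 0, 5, stride = 1))
  coarse <- suppressWarnings(extract_we(tree, 0, 5, stride = 10))
  expect_gte(length(fine), 1)
  expect_length(coarse, length(fine))
  for (i in seq_along(fine)) {
    expect_identical(length(coarse[[i]]$symbols),
                     as.integer(ceiling(length(fine[[i]]$symbols) / 10)))
  }
  expect_error(extract_we(tree, 0, 5, stride = 3), "divide")
})

test_that("segments starting in target without a source visit are skipped", {
  tree <- make_chain_tree(rbind(c(9L, 9L), c(9L, 9L)))
  expect_message(paths <- extract_we(tree, 0, 9), "skipped")
  expect_length(paths, 0)
})

test_that("trajectory_tree validates structure", {
  expect_error(trajectory_tree(data.frame(iteration = 1L, seg_id = 0L,
                                          parent_id = -1L, weight = 1),
                               matrix(0L, 1, 3), tau_frames = 2),
               "tau_frames")
  segments <- data.frame(iteration = c(1L, 2L), seg_id = c(0L, 0L),
                         parent_id = c(-1L, 5L), weight = c(1, 1))
  expect_error(trajectory_tree(segments, matrix(0L, 2, 2), 2),
               "malformed tree")
  expect_warning(trajectory_tree(
    data.frame(iteration = 1L, seg_id = 0L, parent_id = -1L, weight = 0.4),
    matrix(0L, 1, 2), 2), "sum to 1")
})
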