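fake_tree <- function(heights, n_leaves) {
  structure(list(merges = data.frame(height = heights),
                 n_leaves = n_leaves), class = "linkage_tree")
}

test_that("ward_linkage handles trivial matrices and validates input", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2)
  tree <- ward_linkage(d)
  expect_identical(tree$n_leaves, 2L)
  expect_equal(tree$merges$height, 0.4)
  # three identical pathways merge at height zero
  d0 <- matrix(0, 3, 3)
  expect_true(all(ward_linkage(d0)$merges$height == 0))
  expect_error(ward_linkage(matrix(0, 1, 1)), "too few")
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(ward_linkage(bad), "symmetric")
})

test_that("ward_linkage matches brute-force Lance-Williams agglomeration", {
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(5:9, 1)
    m <- matrix(runif(n * n), n)
    d <- (m + t(m)) / 2; diag(d) <- 0
    tree <- ward_linkage(d)
    expect_equal(sort(tree$merges$height), sort(oracle_ward_heights(d)),
                 tolerance = 1e-8)
  }
})

test_that("two tight groups merge internally before the final bridge", {
  strs <- c(rep("0345", 3), rep("0125", 3))
  d <- pairwise_distances(as.list(strs))
  tree <- ward_linkage(d)
  h <- tree$merges$height
  expect_gt(h[length(h)], max(h[-length(h)]))
  expect_equal(tree$merges$size[length(h)], 6)
})

test_that("suggest_cut picks the midpoint of the largest gap", {
  cut <- suggest_cut(fake_tree(c(0.1, 0.15, 0.9), 4))
  expect_gt(cut$cut_height, 0.15); expect_lt(cut$cut_height, 0.9)
  expect_equal(cut$cut_height, (0.15 + 0.9) / 2)
  expect_identical(cut$n_classes, 2L)
  # exhaustive check: the returned cut bounds the maximal gap
  set.seed(17)
  for (rep in 1:20) {
    h <- sort(runif(sample(3:10, 1)))
    tree <- fake_tree(h, length(h) + 1)
    cut <- suggest_cut(tree)
    gaps <- diff(h)
    g <- length(h) - cut$n_classes + 1  # gap index bounding the cut
    expect_equal(gaps[g], max(gaps))
    expect_true(cut$cut_height > h[g] && cut$cut_height < h[g + 1])
  }
})

test_that("degenerate dendrograms give one class with a warning", {
  expect_warning(cut <- suggest_cut(fake_tree(c(0.3, 0.3, 0.3), 4)),
                 "degenerate")
  expect_identical(cut$n_classes, 1L)
  expect_warning(suggest_cut(fake_tree(0, 2)), "degenerate")
})

test_that("gap ties break toward fewer classes", {
  cut <- suggest_cut(fake_tree(c(0.1, 0.5, 0.9), 4))  # two equal gaps
  expect_identical(cut$n_classes, 2L)
})

test_that("assign_classes cuts and orders labels by total weight", {
  strs <- c(rep("0345", 2), rep("0125", 4))
  d <- pairwise_distances(as.list(strs))
  tree <- ward_linkage(d)
  expect_identical(assign_classes(tree, max(tree$merges$height) + 1),
                   rep(1L, 6))
  expect_length(unique(assign_classes(tree, -1)), 6)
  cls <- assign_classes(tree, suggest_cut(tree)$cut_height)
  # class 1 is the larger (equal-weight) group
  expect_identical(cls, c(2L, 2L, 1L, 1L, 1L, 1L))
  # weights can flip the ordering
  w <- c(10, 10, 1, 1, 1, 1)
  cls_w <- assign_classes(tree, suggest_cut(tree)$cut_height, weights = w)
  expect_identical(cls_w, c(1L, 1L, 2L, 2L, 2L, 2L))
})

test_that("partition is invariant to pathway input order", {
  world <- make_two_route_paths(seed = 2, n_paths = 30)
  d <- pairwise_distances(world$paths, condense_level = 2)
  tree <- ward_linkage(d)
  cls <- assign_classes(tree, suggest_cut(tree)$cut_height)
  set.seed(99)
  perm <- sample(length(world$paths))
  d2 <- pairwise_distances(world$paths[perm], condense_level = 2)
  tree2 <- ward_linkage(d2)
  cls2 <- assign_classes(tree2, suggest_cut(tree2)$cut_height)
  expect_gte(two_class_agreement(cls2, cls[perm] ), 1)  # identical partition
})

test_that("class probabilities are weight fractions summing to one", {
  paths <- lapply(1:4, function(i) pathway("012", weight = 0.25, id = i))
  expect_equal(unname(class_probabilities(paths, c(1, 1, 1, 2))),
               c(0.75, 0.25))
  expect_equal(unname(class_probabilities(paths, rep(1, 4))), 1)
  p <- class_probabilities(paths, c(2, 1, 1, 2))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_error(class_probabilities(list(pathway("01", weight = NA)), 1),
               NA)  # NA weights default to 1
})

test_that("duration lists are complete and class-resolved", {
  paths <- list(pathway(rep(1, 12), event_duration_frames = 12),
                pathway(rep(1, 3), event_duration_frames = 3),
                pathway(rep(1, 7), event_duration_frames = 7))
  durs <- duration_histograms(paths, c(1, 1, 2))
  expect_equal(durs[["1"]], c(12, 3))
  expect_equal(durs[["2"]], 7)
  with_time <- duration_histograms(paths, c(1, 1, 2), frame_interval = 4)
  expect_equal(attr(with_time[["1"]], "time"), c(48, 12))
})

test_that("network edges accumulate condensed transitions and weights", {
  p <- pathway(c(0L, 3L, 1L), weight = 0.4)
  edges <- network_edges(list(p, p), condense_level = 0)
  all_rows <- edges[edges$class == "all", ]
  expect_equal(all_rows$from, c(0, 3))
  expect_equal(all_rows$to, c(3, 1))
  expect_equal(all_rows$weight, c(0.8, 0.8))
  nodes <- attr(edges, "nodes")
  expect_equal(nodes$weight[nodes$class == "all" & nodes$state == 3], 0.8)
  # condensation collapses dwell repeats before counting
  pd <- pathway(c(0L, 0L, 3L, 3L, 1L), weight = 1)
  e2 <- network_edges(list(pd), condense_level = 2)
  expect_equal(nrow(e2[e2$class == "all", ]), 2)
  expect_identical(nrow(network_edges(list())), 0L)
})

test_that("two-route classes have disjoint interior edges", {
  world <- make_two_route_paths(seed = 6)
  rep <- suppressWarnings(class_report(world$paths, condense_level = 2))
  edges <- rep$edges
  interior <- function(cl) {
    e <- edges[edges$class == cl & edges$from != 0 & edges$to != 5 &
                 edges$from != 5, ]
    paste(e$from, e$to)
  }
  # the route-discriminating transitions never co-occur across classes
  expect_true(("3 4" %in% interior("1")) != ("3 4" %in% interior("2")))
  expect_true(("1 2" %in% interior("1")) != ("1 2" %in% interior("2")))
})

test_that("class_report assembles a consistent report with guardrails", {
  world <- make_two_route_paths(seed = 4)
  rep <- suppressWarnings(class_report(world$paths, condense_level = 2))
  expect_identical(rep$n_classes, 2L)
  expect_equal(sum(rep$class_prob), 1, tolerance = 1e-9)
  expect_length(rep$class_of, length(world$paths))
  expect_true(all(rep$class_of %in% 1:2))
  expect_identical(sort(as.integer(names(rep$durations))), 1:2)
  expect_gte(two_class_agreement(rep$class_of, world$routes), 0.9)
  # guardrails: small ensembles and small classes warn
  small <- world$paths[1:6]
  w_small <- capture_warnings(class_report(small))
  expect_true(any(grepl("fewer than 50 pathways", w_small)))
  two_state <- list(pathway("01"), pathway("01"), pathway("011"))
  w <- capture_warnings(class_report(two_state, condense_level = 0))
  expect_true(any(grepl("fewer than 3 discrete states", w)))
  # explicit n_classes override
  rep3 <- suppressWarnings(class_report(world$paths, n_classes = 3))
  expect_identical(rep3$n_classes, 3L)
})
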