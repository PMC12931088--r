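# build a minimal one-time-step graph by hand: root + one filopodium
toy_graph <- function() {
  g <- skeleton_graph()
  g <- add_root(g, 1L, 0L, c(0, 0, 0))
  tip <- filotrace:::add_node_(g, c(0.5, 0, 0), "tip", 0L, 1L, 1L)
  g <- tip$graph
  base <- filotrace:::add_node_(g, c(0.2, 0, 0), "base", 0L, 1L, 1L)
  g <- base$graph
  fil <- cbind(seq(0.5, 0.2, by = -0.1), 0, 0)
  g <- filotrace:::add_edge_(g, tip$id, base$id, "filopodium", 0L, 1L, fil, 1L)$graph
  g <- filotrace:::add_edge_(g, base$id, 1L, "axon_terminal", 0L, 1L,
                             cbind(c(0.2, 0.1, 0), 0, 0), 1L)$graph
  g$next_track_id <- 2L
  g
}

test_that("path_length sums polylines, including branches distal to the base", {
  # straight polyline of 6 points spaced 0.1 um
  g <- skeleton_graph()
  g <- add_root(g, 1L, 0L, c(0.9, 0, 0))
  tip <- filotrace:::add_node_(g, c(0, 0, 0), "tip", 0L, 1L, 1L)
  g <- tip$graph
  base <- filotrace:::add_node_(g, c(0.5, 0, 0), "base", 0L, 1L, 1L)
  g <- base$graph
  g <- filotrace:::add_edge_(g, tip$id, base$id, "filopodium", 0L, 1L,
                             cbind(seq(0, 0.5, by = 0.1), 0, 0), 1L)$graph
  g <- filotrace:::add_edge_(g, base$id, 1L, "axon_terminal", 0L, 1L,
                             cbind(c(0.5, 0.9), 0, 0), 1L)$graph
  expect_equal(path_length(g, 1L, 0L), 0.5, tolerance = 1e-12)

  # add a 0.2 um branch between tip and base: total length 0.7
  br <- filotrace:::add_node_(g, c(0.3, 0.2, 0), "tip", 0L, 1L, 1L)
  g <- br$graph
  g <- filotrace:::add_edge_(g, br$id, base$id, "filopodium", 0L, 1L,
                             rbind(c(0.3, 0.2, 0), c(0.3, 0.1, 0), c(0.5, 0, 0)),
                             1L)$graph
  expect_equal(path_length(g, 1L, 0L), 0.5 + 0.1 + sqrt(0.04 + 0.01),
               tolerance = 1e-12)
  expect_error(path_length(g, 99L, 0L), "no filopodium")
})

test_that("path_length is invariant under rigid motion", {
  g <- toy_graph()
  L0 <- path_length(g, 1L, 0L)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  shift <- c(3, -2, 1)
  g$nodes[, c("x", "y", "z")] <-
    t(R %*% t(as.matrix(g$nodes[, c("x", "y", "z")]))) +
    matrix(shift, nrow(g$nodes), 3, byrow = TRUE)
  g$edges$polyline <- lapply(g$edges$polyline, function(m)
    t(R %*% t(m)) + matrix(shift, nrow(m), 3, byrow = TRUE))
  expect_equal(path_length(g, 1L, 0L), L0, tolerance = 1e-12)
})

test_that("validate_graph reports structural violations", {
  g <- toy_graph()
  expect_length(validate_graph(g), 0)

  # duplicate root in one (axon, time step)
  g2 <- g
  g2 <- filotrace:::add_node_(g2, c(1, 1, 0), "root", 0L, 1L)$graph
  expect_true(any(grepl("2 root nodes", validate_graph(g2))))

  # cycle: an extra edge between existing nodes breaks the tree property
  g3 <- g
  g3 <- filotrace:::add_edge_(g3, 2L, 1L, "axon_terminal", 0L, 1L,
                              rbind(c(0.5, 0, 0), c(0, 0, 0)))$graph
  expect_true(any(grepl("not a tree", validate_graph(g3))))

  # well-formed simulator output is valid
  sim <- simulate_series(sim_config(n_frames = 2, n_filopodia = 3, seed = 2))
  expect_length(validate_graph(sim$truth$graph), 0)
})

test_that("native graph files round-trip losslessly", {
  path <- withr::local_tempfile(fileext = ".json")
  g <- toy_graph()
  write_graph(g, path)
  back <- read_graph(path)
  expect_equal(back$nodes, g$nodes)
  expect_equal(back$edges$polyline, g$edges$polyline)
  expect_equal(back$edges[, names(back$edges) != "polyline"],
               g$edges[, names(g$edges) != "polyline"])
  expect_identical(back$next_track_id, g$next_track_id)

  # empty graph round-trips too
  write_graph(skeleton_graph(), path)
  empty <- read_graph(path)
  expect_identical(nrow(empty$nodes), 0L)
  expect_length(validate_graph(empty), 0)
})

test_that("SWC export has one leaf of tip type per filopodium", {
  sim <- simulate_series(sim_config(n_frames = 1, n_filopodia = 3, seed = 4))
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(sim$truth$graph, 0L, path)
  swc <- read.table(path, comment.char = "#",
                    col.names = c("id", "type", "x", "y", "z", "r", "parent"))
  parents <- swc$parent[swc$parent > 0]
  leaves <- setdiff(swc$id, parents)
  expect_length(leaves, 3)
  expect_true(all(swc$type[match(leaves, swc$id)] == 6L))
  expect_identical(sum(swc$type == 1L), 1L)  # one soma/root sample
})

test_that("inserting then deleting a filopodium restores the graph", {
  sc <- small_scene(n_frames = 1, n_filopodia = 2, seed = 13)
  prep <- sc$prep
  g0 <- prep$graph
  res <- add_filopodium(g0, 0L, unlist(sc$seeds$tip_seeds[1, c("x", "y", "z")]),
                        prep$series$frames[[1]], prep$trees[[1]])
  g1 <- delete_filopodium(res$graph, 0L, res$track_id)
  expect_equal(g1$nodes, g0$nodes)
  expect_equal(g1$edges$polyline, g0$edges$polyline)
  expect_equal(nrow(g1$edges), nrow(g0$edges))
})
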