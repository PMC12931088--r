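test_that("edge weight matches hand-evaluated values", {
  p <- filo_params()   # c = 50, i_max = 100
  # bright-bright along x: 0.1 + 100/200
  expect_equal(edge_weight(c(0, 0, 0), c(0.1, 0, 0), 255, 255, p), 0.6,
               tolerance = 1e-12)
  # dark voxels clamped to 1: 0.1 + 100/2
  expect_equal(edge_weight(c(0, 0, 0), c(0.1, 0, 0), 0, 0, p), 50.1,
               tolerance = 1e-12)
  # c = 0 leaves the pure Euclidean step
  p0 <- filo_params(c = 0)
  expect_equal(edge_weight(c(0, 0, 0), c(0.1, 0, 0), 40, 200, p0), 0.1,
               tolerance = 1e-12)
  # anisotropic diagonal step
  expect_equal(edge_weight(c(0, 0, 0), c(0.1, 0.1, 0.5), 255, 255, p),
               sqrt(0.01 + 0.01 + 0.25) + 0.5, tolerance = 1e-12)
  # capping: intensities at or above i_max are equivalent
  expect_identical(edge_weight(c(0, 0, 0), c(0.1, 0, 0), 100, 150, p),
                   edge_weight(c(0, 0, 0), c(0.1, 0, 0), 255, 255, p))
  expect_error(edge_weight(c(0, 0, 0), c(0.3, 0, 0), 10, 10, p), "neighbors")
  expect_error(edge_weight(c(0, 0, 0), c(0, 0, 0), 10, 10, p), "neighbors")
})

test_that("shortest-path trees agree exactly with a brute-force oracle", {
  p <- filo_params()
  set.seed(101)
  for (rep in 1:20) {
    d <- c(sample(4:6, 1), sample(4:6, 1), sample(2:3, 1))
    img <- grid_image(array(sample(0:255, prod(d), TRUE), dim = d), SPACING)
    root <- c(sample(d[1], 1), sample(d[2], 1), sample(d[3], 1))
    tree <- build_tree(img, root, p)
    expect_identical(tree$cost, oracle_dijkstra(img, root, p))
    expect_identical(tree$cost[filotrace:::linear_index(root, d)], 0)
  }
})

test_that("traces follow predecessor chains to the root", {
  img <- ramp_image(c(10L, 8L, 3L))
  tree <- build_tree(img, c(5, 5, 2))
  # start = root: single point, zero length
  p0 <- trace_to_root(tree, c(5, 5, 2))
  expect_identical(nrow(p0), 1L)
  # adjacent start: two points
  p1 <- trace_to_root(tree, c(6, 5, 2))
  expect_identical(nrow(p1), 2L)
  expect_equal(p1[2, ], voxel_to_world(img, c(5, 5, 2)))
  # endpoints: first row start, last row root, consecutive points 26-neighbors
  p2 <- trace_to_root(tree, c(10, 8, 3))
  expect_equal(p2[1, ], voxel_to_world(img, c(10, 8, 3)))
  expect_equal(p2[nrow(p2), ], voxel_to_world(img, c(5, 5, 2)))
  steps <- abs(diff(filotrace:::quantize_polyline(p2, SPACING, img$origin)))
  expect_true(all(steps <= 1))
})

test_that("a bright tube is traced along its centerline", {
  img <- tube_image(from = c(0.5, 2.0, 1.0), dir = c(1, 0, 0), L = 4)
  tree <- build_tree(img, world_to_voxel(img, c(0.5, 2.0, 1.0)))
  poly <- trace_to_root(tree, world_to_voxel(img, c(4.5, 2.0, 1.0)))
  # stays within one x-y voxel of the known centerline y = 2.0
  expect_true(all(abs(poly[, 2] - 2.0) <= 0.1 + 1e-9))
})

test_that("pairwise traces in the dilated box equal unrestricted traces", {
  p <- filo_params(n_margin = 10L)
  set.seed(55)
  for (rep in 1:10) {
    d <- c(7, 6, 3)
    img <- grid_image(array(sample(0:255, prod(d), TRUE), dim = d), SPACING)
    a <- c(sample(d[1], 1), sample(d[2], 1), sample(d[3], 1))
    b <- c(sample(d[1], 1), sample(d[2], 1), sample(d[3], 1))
    if (all(a == b)) next
    # margin 10 >= lattice size: the dilated box covers the whole lattice,
    # so the path cost must equal the unrestricted optimum from the oracle
    poly <- trace_between(img, a, b, p)
    q <- filotrace:::quantize_polyline(poly, SPACING, img$origin)
    Iv <- pmin(pmax(img$values, 1), p$i_max)
    cost <- 0
    for (k in seq_len(nrow(q) - 1)) {
      cost <- cost + sqrt(sum(((q[k, ] - q[k + 1, ]) * SPACING)^2)) +
        2 * p$c / (Iv[matrix(q[k, ], 1)] + Iv[matrix(q[k + 1, ], 1)])
    }
    expect_equal(cost, oracle_dijkstra(img, b, p)[filotrace:::linear_index(a, d)],
                 tolerance = 1e-9)
  }
  # degenerate: both endpoints equal
  img <- ramp_image(c(6L, 6L, 2L))
  expect_identical(nrow(trace_between(img, c(3, 3, 1), c(3, 3, 1))), 1L)
})

test_that("an L-shaped tube is followed through the dilated search box", {
  # the bend exits the tight bounding box of the endpoints but not the
  # box dilated by n_margin
  dims <- c(40L, 40L, 3L)
  img0 <- array(0, dim = dims)
  cl <- rbind(sweep(outer(seq(0, 1.4, 0.05), c(1, 0, 0)), 2, c(0.5, 0.5, 1), "+"),
              sweep(outer(seq(0.05, 1.4, 0.05), c(0, 1, 0)), 2, c(1.9, 0.5, 1), "+"))
  img0 <- filotrace:::render_tube(img0, dims, SPACING, cl, 200, 0.1, 0.4)
  img <- grid_image(round(img0), SPACING)
  a <- world_to_voxel(img, c(0.5, 0.5, 1))
  b <- world_to_voxel(img, c(1.9, 1.9, 1))
  poly <- trace_between(img, a, b, filo_params(n_margin = 10L))
  # the path must swing out near the corner (1.9, 0.5): the straight chord
  # between the endpoints passes about 1 um from it
  corner_dist <- min(sqrt(rowSums(sweep(poly[, 1:2], 2, c(1.9, 0.5), "-")^2)))
  expect_lt(corner_dist, 0.35)
})

test_that("raising c never lowers a fixed path's cost", {
  img <- ramp_image(c(6L, 6L, 2L))
  a <- c(1, 1, 1); b <- c(6, 6, 2)
  cost_at <- function(cc) {
    tree <- build_tree(img, b, filo_params(c = cc))
    tree$cost[filotrace:::linear_index(a, dim(img))]
  }
  costs <- vapply(c(0, 10, 50, 200), cost_at, numeric(1))
  expect_true(all(diff(costs) >= 0))
  # with c = 0 the traced path length is the minimal 26-connected length
  tree0 <- build_tree(img, b, filo_params(c = 0))
  poly <- trace_to_root(tree0, a)
  expect_equal(filotrace:::polyline_length(poly),
               oracle_dijkstra(img, b, filo_params(c = 0))[
                 filotrace:::linear_index(a, dim(img))],
               tolerance = 1e-12)
})

test_that("trees persist and reload identically", {
  img <- ramp_image(c(8L, 8L, 3L))
  tree <- build_tree(img, c(4, 4, 2))
  path <- withr::local_tempfile(fileext = ".rds")
  save_tree(tree, path)
  back <- load_tree(path)
  expect_identical(back$pred, tree$pred)
  expect_identical(back$cost, tree$cost)
})
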