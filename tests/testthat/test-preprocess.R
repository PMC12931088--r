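test_that("crop box contains the whole terminal and its filopodia", {
  sc <- small_scene(n_frames = 1, n_filopodia = 3, seed = 31)
  f <- sc$sim$series$frames[[1]]
  box <- estimate_crop_box(f, sc$sim$truth$root[1, ])
  expect_false(attr(box, "flagged"))
  # every ground-truth skeleton point lies inside the box
  for (m in sc$sim$truth$graph$edges$polyline) {
    v <- filotrace:::quantize_polyline(m, f$spacing, f$origin)
    expect_true(all(sweep(v, 2, box$lo, ">=") & sweep(v, 2, box$hi, "<=")))
  }
})

test_that("two distant terminals produce mutually exclusive boxes", {
  dims <- c(120L, 50L, 9L)
  arr <- array(0, dims)
  arr <- filotrace:::render_blob(arr, dims, SPACING, c(2.5, 2.5, 2),
                                 c(0.8, 0.8, 1), 200, 0.18)
  arr <- filotrace:::render_blob(arr, dims, SPACING, c(9.5, 2.5, 2),
                                 c(0.8, 0.8, 1), 200, 0.18)
  img <- grid_image(round(arr), SPACING)
  b1 <- estimate_crop_box(img, c(2.5, 2.5, 2))
  b2 <- estimate_crop_box(img, c(9.5, 2.5, 2))
  c2_vox <- world_to_voxel(img, c(9.5, 2.5, 2))
  c1_vox <- world_to_voxel(img, c(2.5, 2.5, 2))
  expect_lt(b1$hi[1], c2_vox[1])
  expect_gt(b2$lo[1], c1_vox[1])
})

test_that("degenerate inputs are flagged", {
  img <- grid_image(array(200, c(20, 20, 4)), SPACING)
  clear_log()
  box <- estimate_crop_box(img, c(0.5, 0.5, 0.5))
  expect_true(attr(box, "flagged"))
  expect_identical(box$lo, c(1L, 1L, 1L))
  expect_identical(box$hi, c(20L, 20L, 4L))

  dark <- grid_image(array(5, c(30, 30, 4)), SPACING)
  clear_log()
  box2 <- estimate_crop_box(dark, c(1.0, 1.0, 0.5))
  expect_true(attr(box2, "flagged"))
  expect_true("root_in_background" %in% filotrace:::log_types())
})

test_that("persistence merging absorbs weak components into bright neighbors", {
  # a bright blob with a dim satellite one background voxel away: plain
  # connected components keeps them apart, the persistence filter merges them
  dims <- c(60L, 30L, 5L)
  arr <- array(0, dims)
  arr[10:20, 10:20, 2:4] <- 220
  arr[23:26, 12:17, 2:4] <- 90    # dim, gap of 2 voxels at 22
  arr[21, 14, 3] <- 60            # bridge-ish voxel below persistence
  img <- grid_image(arr, SPACING)
  p <- filo_params()               # theta 50, persistence 150
  box <- estimate_crop_box(img, c(1.4, 1.4, 1))
  # the dim satellite (max 90 - theta < persistence) is merged in: box
  # reaches past x-voxel 23
  expect_gte(box$hi[1], 23L)
})

test_that("preprocessing anchors the crop box to the propagated root", {
  # short filopodia so the root-anchored box fits the lattice in all frames
  sc <- small_scene(n_frames = 4, n_filopodia = 2, seed = 37,
                    length0 = c(1, 1.5), length_bounds = c(0.25, 2))
  prep <- sc$prep
  # root sits at the same cropped-voxel position in every frame
  expect_identical(nrow(unique(prep$root_voxel)), 1L)
  # equivalently: root_world - box_origin_world is constant per axon
  rel <- vapply(seq_len(4), function(i) {
    rw <- filotrace:::node_pos(prep$graph,
                               filotrace:::root_id(prep$graph, 1L, i - 1L))
    rw - prep$series$frames[[i]]$origin
  }, numeric(3))
  for (i in 2:4) expect_equal(rel[, i], rel[, 1], tolerance = 1e-12)
  # trees exist and are rooted at the anchored voxel
  for (i in 1:4)
    expect_identical(prep$trees[[i]]$root_voxel, prep$root_voxel[i, ])
})

test_that("root propagation follows drift and falls back on noise", {
  sim <- simulate_series(sim_config(n_frames = 3, n_filopodia = 0, seed = 43,
                                    drift = c(0.2, -0.1, 0)))
  g <- skeleton_graph()
  g <- add_root(g, 1L, 0L, sim$truth$root[1, ])
  g <- propagate_root(sim$series, g, 0L)
  g <- propagate_root(sim$series, g, 1L)
  for (t in 0:2) {
    rw <- filotrace:::node_pos(g, filotrace:::root_id(g, 1L, t))
    expect_lt(xy_vox_error(rw, sim$truth$root[t + 1, ]), 1.5)
  }

  # frame replaced by noise: the root keeps its position and warns
  set.seed(3)
  noisy <- sim$series
  noisy$frames[[3]]$values <- round(pmin(pmax(
    array(rnorm(prod(dim(noisy$frames[[3]]$values)), 10, 5),
          dim(noisy$frames[[3]]$values)), 0), 255))
  g2 <- skeleton_graph()
  g2 <- add_root(g2, 1L, 0L, sim$truth$root[1, ])
  g2 <- propagate_root(noisy, g2, 0L)
  clear_log()
  g2 <- propagate_root(noisy, g2, 1L)
  expect_true("low_ncc_root" %in% filotrace:::log_types())
  p1 <- filotrace:::node_pos(g2, filotrace:::root_id(g2, 1L, 1L))
  p2 <- filotrace:::node_pos(g2, filotrace:::root_id(g2, 1L, 2L))
  expect_identical(p1, p2)
})

test_that("preprocessed datasets reload identically from disk", {
  dir <- withr::local_tempdir()
  sim <- simulate_series(sim_config(n_frames = 2, n_filopodia = 2, seed = 47))
  seeds <- write_seeds(sim)
  prep <- run_preprocess(sim$series, seeds$root_seeds, out_dir = dir)[[1]]
  back <- read_prep(file.path(dir, "axon1"))
  expect_identical(back$series$frames[[1]]$values * 1.0,
                   prep$series$frames[[1]]$values * 1.0)
  expect_equal(back$series$frames[[2]]$origin, prep$series$frames[[2]]$origin)
  expect_identical(back$trees[[1]]$pred, prep$trees[[1]]$pred)
  expect_identical(back$trees[[2]]$cost, prep$trees[[2]]$cost)
  expect_equal(back$graph$nodes, prep$graph$nodes)
})
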