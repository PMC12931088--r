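test_that("an exact Gaussian tube profile scores near zero", {
  # noise-free tube: the transverse profile is the model's ideal case
  img <- tube_image(from = c(1, 2, 2), dir = c(1, 0, 0), L = 4, peak = 200,
                    sxy = 0.15)
  r_tube <- gaussianness(img, c(3, 2, 2), c(1, 0, 0))
  expect_lt(r_tube, 12)  # interpolation + quantization error only

  # uniform bright disc much wider than r_max (axon-body-like) scores far
  # higher than the tube
  body <- array(0, c(60, 40, 9))
  body[10:50, 5:35, 2:6] <- 200
  body_img <- grid_image(body, SPACING)
  r_body <- gaussianness(body_img, c(3, 2, 2), c(1, 0, 0))
  expect_gt(r_body, 5 * r_tube)

  # constant image: the fit degenerates to the constant, rmsd 0
  const <- grid_image(array(120, c(20, 20, 5)), SPACING)
  expect_equal(gaussianness(const, c(1, 1, 1), c(1, 0, 0)), 0,
               tolerance = 1e-9)

  expect_error(gaussianness(img, c(3, 2, 2), c(0, 0, 0)), "tangent")
})

test_that("the estimated base sits near the tube-body junction", {
  sc <- small_scene(n_frames = 1, n_filopodia = 1, seed = 23, walk_sd = 0)
  f <- sc$prep$series$frames[[1]]
  tipw <- unlist(sc$seeds$tip_seeds[1, c("x", "y", "z")])
  poly <- trace_to_root(sc$prep$trees[[1]], world_to_voxel(f, tipw))
  be <- estimate_base(f, poly)
  expect_false(be$flagged)
  expect_lt(xy_vox_error(be$point, sc$sim$truth$base_pos[1, , 1]), 3)
  # the estimate lies on the input polyline
  expect_true(any(rowSums(sweep(poly, 2, be$point, "-")^2) < 1e-18))
})

test_that("a path entirely inside a tube (no body) falls back, flagged", {
  img <- tube_image(from = c(0.5, 2, 2), dir = c(1, 0, 0), L = 4.5,
                    noise_sd = 3)
  tree <- build_tree(img, world_to_voxel(img, c(0.6, 2, 2)))
  poly <- trace_to_root(tree, world_to_voxel(img, c(4.8, 2, 2)))
  be <- estimate_base(img, poly)
  expect_true(be$flagged)
  expect_identical(be$index, nrow(poly) - 1L)  # root-side endpoint
})

test_that("branch-induced RMSD peaks do not trigger the base", {
  # main tube toward +x with a side branch crossing mid-path, body at the
  # proximal end: the branch causes a local RMSD peak that must be skipped
  dims <- c(70L, 46L, 9L)
  arr <- array(0, dims)
  main <- sweep(outer(seq(0, 3.5, 0.05), c(1, 0, 0)), 2, c(1.4, 2.3, 2), "+")
  branch <- sweep(outer(seq(0, 1.2, 0.05), c(0.55, 0.83, 0)), 2,
                  c(3.2, 2.3, 2), "+")
  arr <- filotrace:::render_tube(arr, dims, SPACING, main, 180, 0.13, 0.4)
  arr <- filotrace:::render_tube(arr, dims, SPACING, branch, 180, 0.13, 0.4)
  arr <- filotrace:::render_blob(arr, dims, SPACING, c(1.0, 2.3, 2),
                                 c(0.8, 0.8, 1.0), 200, 0.18)
  set.seed(17)
  img <- grid_image(round(pmin(pmax(arr + rnorm(length(arr), 0, 5), 0), 255)),
                    SPACING)
  tree <- build_tree(img, world_to_voxel(img, c(1.0, 2.3, 2)))
  poly <- trace_to_root(tree, world_to_voxel(img, c(4.9, 2.3, 2)))
  be <- estimate_base(img, poly)
  expect_false(be$flagged)
  # true junction where the tube meets the body surface, x ~ 1.8
  expect_lt(xy_vox_error(be$point, c(1.8, 2.3, 2)), 3)
  # and decidedly not at the branch crossing (x ~ 3.2)
  expect_gt(abs(be$point[1] - 3.2), 0.5)
})

test_that("base detection is invariant to affine intensity rescaling", {
  sc <- small_scene(n_frames = 1, n_filopodia = 1, seed = 29, walk_sd = 0,
                    noise_sd = 0)
  f <- sc$prep$series$frames[[1]]
  tipw <- unlist(sc$seeds$tip_seeds[1, c("x", "y", "z")])
  poly <- trace_to_root(sc$prep$trees[[1]], world_to_voxel(f, tipw))
  be1 <- estimate_base(f, poly)
  f2 <- f
  f2$values <- f$values * 0.6 + 30   # gain + offset, stays inside [0, 255]
  be2 <- estimate_base(f2, poly)
  expect_identical(be2$index, be1$index)
})

test_that("paths too short for the smoothing window fall back, flagged", {
  img <- tube_image()
  short_poly <- cbind(seq(2.0, 1.6, by = -0.1), 2, 2)
  be <- estimate_base(img, short_poly, filo_params())
  expect_true(be$flagged)
  expect_identical(be$index, nrow(short_poly) - 1L)
})
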