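# hand-built insertion fixture: voxel-aligned polylines on a small lattice
straight_poly <- function(x_from, x_to, y = 0.4, z = 0.5) {
  cbind(seq(x_from, x_to, by = if (x_to < x_from) -0.1 else 0.1), y, z)
}

test_that("insert_path classifies junctions by their position on the host path", {
  img <- ramp_image(c(40L, 40L, 3L))
  g <- skeleton_graph()
  g <- add_root(g, 1L, 0L, c(0.4, 0.4, 0.5))

  # first filopodium: no junction, full path inserted
  p1 <- straight_poly(2.0, 0.4)
  r1 <- insert_path(g, p1, 0L, 1L, img, base_index = 12L)  # base at x = 0.9
  g <- r1$graph
  expect_false(r1$merged)
  expect_identical(sort(unique(g$nodes$type)), c("base", "root", "tip"))
  expect_equal(path_length(g, r1$track_id, 0L), 1.1, tolerance = 1e-9)

  # second path joins between tip and base (x = 1.8): integrated branch,
  # same track, branch length added
  p2 <- rbind(cbind(1.8, seq(1.0, 0.5, by = -0.1), 0.5), c(1.8, 0.4, 0.5))
  r2 <- insert_path(g, p2, 0L, 1L, img, base_index = 3L)
  g <- r2$graph
  expect_true(r2$merged)
  expect_identical(r2$track_id, r1$track_id)
  expect_true("branching" %in% g$nodes$type)
  expect_equal(path_length(g, r1$track_id, 0L), 1.1 + 0.6, tolerance = 1e-9)

  # third path joins below the base (x = 0.7, on the terminal path):
  # independent filopodium with its own track
  p3 <- rbind(cbind(0.7, seq(1.2, 0.5, by = -0.1), 0.5), c(0.7, 0.4, 0.5))
  r3 <- insert_path(g, p3, 0L, 1L, img, base_index = 4L)
  g <- r3$graph
  expect_false(r3$merged)
  expect_false(r3$track_id == r1$track_id)
  expect_length(validate_graph(g), 0)
  # both filopodia report their own lengths
  expect_equal(path_length(g, r3$track_id, 0L), 0.3, tolerance = 1e-9)
})

test_that("a junction right at the host base starts an independent track", {
  img <- ramp_image(c(40L, 40L, 3L))
  g <- skeleton_graph()
  g <- add_root(g, 1L, 0L, c(0.4, 0.4, 0.5))
  r1 <- insert_path(g, straight_poly(2.0, 0.4), 0L, 1L, img, base_index = 12L)
  g <- r1$graph
  # joins the filopodium edge 0.1 um from its base: within branch_margin
  p2 <- rbind(cbind(1.0, seq(1.0, 0.5, by = -0.1), 0.5), c(1.0, 0.4, 0.5))
  r2 <- insert_path(g, p2, 0L, 1L, img, base_index = 6L)
  expect_false(r2$merged)
  expect_false(r2$track_id == r1$track_id)
  expect_length(validate_graph(r2$graph), 0)
})

test_that("propagation keeps track identity and the graphs valid", {
  sc <- small_scene(n_frames = 4, n_filopodia = 3, seed = 7)
  rec <- reconstruct_axon(sc$prep, sc$seeds$tip_seeds)
  g <- rec$graph
  expect_length(validate_graph(g), 0)
  for (t in 0:3) {
    tr <- tracks_at(g, t)
    expect_identical(anyDuplicated(tr), 0L)     # no shared tracks in a frame
  }
  # every seeded filopodium survives all four frames with its own track
  expect_identical(nrow(rec$seed_tracks), 3L)
  for (tid in rec$seed_tracks$track_id)
    for (t in 0:3)
      expect_false(is.na(filotrace:::track_node(g, tid, t, "tip")))
})

test_that("shrinking below the minimum length removes the filopodium", {
  # programmed shrink: 1.5 -> 1.2 -> 0.28 um; the last value is far below
  # the 0.5 um threshold, so quantization cannot flip the decision
  traj <- list(c(1.5, 1.2, 0.28, 0.28),
               c(1.5, 1.6, 1.7, 1.8))
  sc_sim <- simulate_series(sim_config(n_frames = 4, n_filopodia = 2,
                                       birth = c(0L, 0L), death = c(3L, 3L),
                                       length_traj = traj, seed = 51,
                                       walk_sd = 0))
  seeds <- write_seeds(sc_sim)
  prep <- run_preprocess(sc_sim$series, seeds$root_seeds)[[1]]
  clear_log()
  rec <- reconstruct_axon(prep, seeds$tip_seeds)
  tid1 <- rec$seed_tracks$track_id[rec$seed_tracks$seed_label == 1]
  tid2 <- rec$seed_tracks$track_id[rec$seed_tracks$seed_label == 2]
  # track 1 ends when its true length drops below 0.5 um
  expect_false(is.na(filotrace:::track_node(rec$graph, tid1, 1L, "tip")))
  expect_true(is.na(filotrace:::track_node(rec$graph, tid1, 2L, "tip")))
  # the healthy track continues
  expect_false(is.na(filotrace:::track_node(rec$graph, tid2, 3L, "tip")))
  # and the removal is recorded as a retraction event
  evs <- Filter(function(e) e$type == "retraction", get_log())
  expect_true(any(vapply(evs, function(e)
    e$track_id == tid1 && e$t == 2, logical(1))))
})

test_that("a filopodium that disappears ends its track (death event)", {
  sim <- simulate_series(sim_config(n_frames = 3, n_filopodia = 2,
                                    birth = c(0L, 0L), death = c(1L, 2L),
                                    seed = 53, walk_sd = 0))
  seeds <- write_seeds(sim)
  prep <- run_preprocess(sim$series, seeds$root_seeds)[[1]]
  clear_log()
  rec <- reconstruct_axon(prep, seeds$tip_seeds)
  tid1 <- rec$seed_tracks$track_id[rec$seed_tracks$seed_label == 1]
  expect_false(is.na(filotrace:::track_node(rec$graph, tid1, 1L, "tip")))
  expect_true(is.na(filotrace:::track_node(rec$graph, tid1, 2L, "tip")))
  expect_true("retraction" %in% filotrace:::log_types())
})

test_that("move_tip repairs a corrupted propagation", {
  sc <- small_scene(n_frames = 2, n_filopodia = 1, seed = 57, walk_sd = 0)
  rec <- reconstruct_axon(sc$prep, sc$seeds$tip_seeds)
  tid <- rec$seed_tracks$track_id[1]
  # corrupt: drag the tip 0.5 um sideways off the tube
  true_tip <- sc$sim$truth$tip_pos[1, , 2]
  g_bad <- apply_edit(rec$graph,
                      list(op = "move_tip", t = 1L, track_id = tid,
                           pos = true_tip + c(0, 0.5, 0)),
                      sc$prep$series, sc$prep$trees)
  # repair: move it back to the true tip; the retraced path must
  # re-coincide with the centerline
  g_fix <- apply_edit(g_bad,
                      list(op = "move_tip", t = 1L, track_id = tid,
                           pos = true_tip),
                      sc$prep$series, sc$prep$trees)
  tip <- filotrace:::node_pos(g_fix, filotrace:::track_node(g_fix, tid, 1L, "tip"))
  expect_lt(xy_vox_error(tip, true_tip), 1)
  expect_length(validate_graph(g_fix), 0)
})

test_that("match_filopodium links tracks across frames and extends lifetime", {
  sc <- small_scene(n_frames = 2, n_filopodia = 1, seed = 59, walk_sd = 0)
  prep <- sc$prep
  # seed the same filopodium independently at both frames: two 1-step tracks
  g <- prep$graph
  for (t in 0:1) {
    res <- add_filopodium(g, t, sc$sim$truth$tip_pos[1, , t + 1],
                          prep$series$frames[[t + 1]], prep$trees[[t + 1]])
    g <- res$graph
  }
  st0 <- filopodia_stats(g, 1)
  expect_identical(nrow(st0$summary), 2L)
  expect_true(all(st0$summary$lifetime_min == 1))
  tr <- sort(st0$summary$track_id)
  g2 <- apply_edit(g, list(op = "match_filopodium", t = 0L, track_id = tr[1],
                           t2 = 1L, track_id2 = tr[2]),
                   prep$series, prep$trees)
  st1 <- filopodia_stats(g2, 1)
  expect_identical(nrow(st1$summary), 1L)
  expect_identical(st1$summary$lifetime_min, 2)
})

test_that("move_base and move_edge retrace while keeping the graph valid", {
  sc <- small_scene(n_frames = 1, n_filopodia = 1, seed = 61, walk_sd = 0)
  rec <- reconstruct_axon(sc$prep, sc$seeds$tip_seeds)
  tid <- rec$seed_tracks$track_id[1]
  base0 <- filotrace:::node_pos(rec$graph,
                                filotrace:::track_node(rec$graph, tid, 0L, "base"))
  # drag the base one path-step toward the tip
  tip0 <- filotrace:::node_pos(rec$graph,
                               filotrace:::track_node(rec$graph, tid, 0L, "tip"))
  new_base <- base0 + 0.2 * (tip0 - base0) / sqrt(sum((tip0 - base0)^2))
  g2 <- apply_edit(rec$graph, list(op = "move_base", t = 0L, track_id = tid,
                                   pos = new_base),
                   sc$prep$series, sc$prep$trees)
  expect_length(validate_graph(g2), 0)
  b2 <- filotrace:::node_pos(g2, filotrace:::track_node(g2, tid, 0L, "base"))
  expect_lt(sqrt(sum((b2 - new_base)^2)), 0.25)

  # retrace through a supporting point on the tube
  mid <- (tip0 + base0) / 2
  g3 <- apply_edit(g2, list(op = "move_edge", t = 0L, track_id = tid,
                            via = rbind(mid)),
                   sc$prep$series, sc$prep$trees)
  expect_length(validate_graph(g3), 0)
  expect_false(is.na(filotrace:::track_node(g3, tid, 0L, "tip")))
})
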