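# Filopodia tracking: seed new filopodia from tip annotations, propagate
# every filopodium to the next time step by NCC matching of its tip and base,
# retrace the path on the new frame, apply the retraction rules, and keep
# track IDs consistent. Proofreading is exposed as programmatic edit
# commands, so a full interactive session can be replayed from a file.

#' Add (seed) a filopodium at a time step
#'
#' The tip position is the only required annotation: the path is traced from
#' the tip to the root along the precomputed shortest-path tree and the base
#' is detected automatically on the traced path.
#'
#' @param graph a [skeleton_graph()] with a root at `t`.
#' @param t time step.
#' @param tip_world tip position (world um).
#' @param frame the cropped [grid_image()] at `t`.
#' @param tree the frame's `shortest_path_tree`.
#' @param params a [filo_params()].
#' @param axon_id axon terminal ID.
#' @param track_id optional track to assign (default: new track).
#' @return list with `graph`, `track_id`, `base_required`, `merged`.
#' @export
add_filopodium <- function(graph, t, tip_world, frame, tree,
                           params = filo_params(), axon_id = 1L,
                           track_id = NULL) {
  tipv <- world_to_voxel(frame, tip_world)
  poly <- trace_to_root(tree, tipv)
  if (nrow(poly) < 2) {
    log_event("seed_at_root", t = t, axon_id = axon_id)
    stop("tip seed coincides with the root voxel")
  }
  be <- estimate_base(frame, poly, params)
  if (be$flagged)
    log_event("base_fallback", t = t, axon_id = axon_id)
  res <- insert_path(graph, poly, t, axon_id, frame,
                     base_index = if (be$flagged) NULL else be$index,
                     track_id = track_id,
                     branch_margin = params$branch_margin)
  res
}

nearest_polyline_index <- function(poly, point) {
  which.min(rowSums(sweep(poly, 2, point, "-")^2))
}

# Walk a matched tip outward along the intensity ridge to the distal end of
# the tube. The tube interior is self-similar, so the NCC argmax can sit
# anywhere on a score ridge along the axis and slowly slide toward the base;
# anchoring the tip at the end of the foreground ridge removes that drift.
# `outward` is a world-space direction (away from the root); candidates are
# the 26-neighbors within the forward half-cone, the brightest one is taken
# while it stays at or above the foreground threshold `theta`.
refine_tip_ <- function(frame, tipv, outward, theta, max_steps = 15L) {
  d <- dim(frame$values)
  all_offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  all_offs <- all_offs[rowSums(abs(all_offs)) > 0, ]
  offs_w <- sweep(all_offs, 2, frame$spacing, "*")
  dir0 <- outward / sqrt(sum(outward^2))    # fixed reference: no curving back
  fwd <- (offs_w %*% dir0) / sqrt(rowSums(offs_w^2)) > 0.5
  offs <- all_offs[fwd, , drop = FALSE]
  v <- tipv
  # the stop threshold tracks the brightest ridge voxel seen so far: high
  # enough that the walk can neither overshoot the end cap by more than a
  # voxel nor cross the saddle onto a neighboring filopodium
  runmax <- frame$values[matrix(tipv, 1)]
  for (s in seq_len(max_steps)) {
    cand <- sweep(offs, 2, v, "+")
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] & cand[, 2] >= 1 &
      cand[, 2] <= d[2] & cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[ok, , drop = FALSE]
    if (!nrow(cand)) break
    ints <- frame$values[cand]
    b <- which.max(ints)
    if (ints[b] < max(theta, 0.9 * runmax)) break
    v <- cand[b, ]
    runmax <- max(runmax, ints[b])
  }
  # backward trim: an overshoot onto the decaying end cap would otherwise
  # persist across frames (the template re-centers on it); climb back toward
  # the ridge while the current voxel is well below the ridge intensity
  bwd <- (offs_w %*% dir0) / sqrt(rowSums(offs_w^2)) < -0.5
  offs_b <- all_offs[bwd, , drop = FALSE]
  for (s in seq_len(5L)) {
    if (frame$values[matrix(v, 1)] >= max(theta, 0.85 * runmax)) break
    cand <- sweep(offs_b, 2, v, "+")
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] & cand[, 2] >= 1 &
      cand[, 2] <= d[2] & cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[ok, , drop = FALSE]
    if (!nrow(cand)) break
    ints <- frame$values[cand]
    b <- which.max(ints)
    if (ints[b] <= frame$values[matrix(v, 1)]) break
    v <- cand[b, ]
  }
  v
}

#' Propagate all filopodia from time step t to t+1
#'
#' For every filopodium at `t` (in ascending track order, so branching
#' outcomes are deterministic): the tip is matched in the next frame with the
#' tip template/search sizes and the base with the base sizes. A tip with no
#' acceptable NCC match — or whose match lies farther than the threshold
#' distance `d` from its previous position — means the filopodium has
#' retracted: no successor is created and the track ends. An unmatched base
#' falls back to its previous location. The successor path is then retraced
#' tip-to-root on the new frame's shortest-path tree, the matched base is
#' projected onto it, and the path is inserted with the same track ID;
#' branching nodes are not propagated but re-emerge from the insertion
#' intersection test. A successor shorter than `l_min` between base and tip
#' is also considered retracted and is removed.
#'
#' @param graph a [skeleton_graph()] reconstructed through time `t`.
#' @param t time step to propagate from.
#' @param series cropped [time_series()].
#' @param trees list of `shortest_path_tree`, one per frame.
#' @param params a [filo_params()].
#' @param axon_id axon terminal ID.
#' @return updated graph.
#' @export
propagate_filopodia <- function(graph, t, series, trees,
                                params = filo_params(), axon_id = 1L) {
  if (t + 2 > length(series$frames)) stop("no tree/frame for t = ", t + 1)
  f0 <- series$frames[[t + 1]]; f1 <- series$frames[[t + 2]]
  tree1 <- trees[[t + 2]]
  g <- graph
  for (tr in tracks_at(g, t, axon_id)) {
    tip_id <- track_node(g, tr, t, "tip")
    base_id <- track_node(g, tr, t, "base")
    tip_w <- node_pos(g, tip_id)
    tipv0 <- world_to_voxel(f0, tip_w)
    mt <- match_template(f0, f1, tipv0, params$tip_template,
                         params$tip_search, params$tip_gamma)
    if (!mt$accepted) {
      log_event("retraction", t = t + 1, track_id = tr, reason = "tip_unmatched",
                ncc = mt$best_ncc)
      next
    }
    # matched tip, refined to the distal end of the local intensity ridge
    poly0 <- trace_to_root(tree1, mt$best_position)
    outward <- if (nrow(poly0) >= 3) poly0[1, ] - poly0[3, ]
               else poly0[1, ] - poly0[nrow(poly0), ]
    tipv1 <- if (sum(outward^2) > 0)
      refine_tip_(f1, mt$best_position, outward, params$theta)
    else mt$best_position
    tip_w1 <- voxel_to_world(f1, tipv1)
    if (sqrt(sum((tip_w1 - tip_w)^2)) > params$d) {
      log_event("retraction", t = t + 1, track_id = tr, reason = "mismatch",
                dist = sqrt(sum((tip_w1 - tip_w)^2)))
      next
    }
    # base: matched, or previous location if the match is unreliable
    if (!is.na(base_id)) {
      base_w <- node_pos(g, base_id)
      mb <- match_template(f0, f1, world_to_voxel(f0, base_w),
                           params$base_template, params$base_search,
                           params$base_gamma)
      base_w1 <- if (mb$accepted) voxel_to_world(f1, mb$best_position)
                 else {
                   log_event("low_ncc_base", t = t + 1, track_id = tr,
                             ncc = mb$best_ncc)
                   base_w
                 }
    } else base_w1 <- NULL

    poly <- trace_to_root(tree1, tipv1)
    if (nrow(poly) < 2) {
      log_event("retraction", t = t + 1, track_id = tr, reason = "tip_at_root")
      next
    }
    bi <- if (!is.null(base_w1)) nearest_polyline_index(poly, base_w1) else NULL
    seg_len <- if (!is.null(bi) && bi >= 2)
      polyline_length(poly[1:bi, , drop = FALSE]) else polyline_length(poly)
    if (seg_len < params$l_min) {
      log_event("retraction", t = t + 1, track_id = tr,
                reason = "short_filopodium", length = seg_len)
      next
    }
    res <- insert_path(g, poly, t + 1, axon_id, f1, base_index = bi,
                       track_id = tr, branch_margin = params$branch_margin)
    g <- res$graph
    if (res$merged && res$track_id != tr)
      log_event("merged_on_propagation", t = t + 1, track_id = tr,
                into = res$track_id)
  }
  g
}

#' Apply a programmatic proofreading edit
#'
#' Replays the low-level operations of interactive proofreading:
#' \describe{
#'   \item{add_filopodium}{`t`, `tip` (world um): trace + base detection +
#'     insertion; new track.}
#'   \item{delete_filopodium}{`t`, `track_id`: remove the filopodium at `t`.}
#'   \item{move_tip}{`t`, `track_id`, `pos`: relocate the tip and retrace.}
#'   \item{move_base}{`t`, `track_id`, `pos`: move the base to the path point
#'     nearest `pos` and rebuild the filopodium around it.}
#'   \item{move_edge}{`t`, `track_id`, `via` (n x 3): retrace the path so it
#'     passes through the supporting points.}
#'   \item{match_filopodium}{`t`, `track_id`, `t2`, `track_id2`: mark the
#'     filopodium `track_id2` at `t2` (and later) as the continuation of
#'     `track_id`, displacing any conflicting assignment.}
#' }
#'
#' @param graph a [skeleton_graph()].
#' @param cmd named list with `op` and the fields above.
#' @param series cropped [time_series()].
#' @param trees per-frame `shortest_path_tree` list.
#' @param params a [filo_params()].
#' @param axon_id axon terminal ID.
#' @return updated graph.
#' @export
apply_edit <- function(graph, cmd, series, trees, params = filo_params(),
                       axon_id = 1L) {
  stopifnot(!is.null(cmd$op))
  t <- as.integer(cmd$t)
  frame <- function(tt) series$frames[[tt + 1]]
  tree <- function(tt) trees[[tt + 1]]
  g <- graph
  switch(cmd$op,
    add_filopodium = {
      add_filopodium(g, t, as.numeric(cmd$tip), frame(t), tree(t), params,
                     axon_id)$graph
    },
    delete_filopodium = delete_filopodium(g, t, as.integer(cmd$track_id)),
    move_tip = {
      tr <- as.integer(cmd$track_id)
      base_w <- node_pos(g, track_node(g, tr, t, "base"))
      g <- delete_filopodium(g, t, tr)
      tipv <- world_to_voxel(frame(t), as.numeric(cmd$pos))
      poly <- trace_to_root(tree(t), tipv)
      bi <- if (length(base_w) == 3 && !any(is.na(base_w)))
        nearest_polyline_index(poly, base_w) else NULL
      insert_path(g, poly, t, axon_id, frame(t), base_index = bi,
                  track_id = tr)$graph
    },
    move_base = {
      tr <- as.integer(cmd$track_id)
      tip_w <- node_pos(g, track_node(g, tr, t, "tip"))
      g <- delete_filopodium(g, t, tr)
      poly <- trace_to_root(tree(t), world_to_voxel(frame(t), tip_w))
      bi <- nearest_polyline_index(poly, as.numeric(cmd$pos))
      insert_path(g, poly, t, axon_id, frame(t), base_index = bi,
                  track_id = tr)$graph
    },
    move_edge = {
      tr <- as.integer(cmd$track_id)
      via <- matrix(as.numeric(unlist(cmd$via)), ncol = 3, byrow = is.list(cmd$via))
      tip_w <- node_pos(g, track_node(g, tr, t, "tip"))
      base_w <- node_pos(g, track_node(g, tr, t, "base"))
      g <- delete_filopodium(g, t, tr)
      pts <- rbind(tip_w, via)
      segs <- list()
      for (i in seq_len(nrow(pts) - 1))
        segs[[i]] <- trace_between(frame(t), world_to_voxel(frame(t), pts[i, ]),
                                   world_to_voxel(frame(t), pts[i + 1, ]),
                                   params)
      tail_seg <- trace_to_root(tree(t),
                                world_to_voxel(frame(t), pts[nrow(pts), ]))
      poly <- dedupe_polyline(do.call(rbind, c(segs, list(tail_seg))))
      bi <- if (length(base_w) == 3 && !any(is.na(base_w)))
        nearest_polyline_index(poly, base_w) else NULL
      insert_path(g, poly, t, axon_id, frame(t), base_index = bi,
                  track_id = tr)$graph
    },
    match_filopodium = {
      tr_a <- as.integer(cmd$track_id); tr_b <- as.integer(cmd$track_id2)
      t2 <- as.integer(cmd$t2)
      sel_n <- !is.na(g$nodes$track_id) & g$nodes$track_id == tr_a &
        g$nodes$time_step >= t2
      sel_e <- !is.na(g$edges$track_id) & g$edges$track_id == tr_a &
        g$edges$time_step >= t2
      if (any(sel_n)) {
        log_event("match_displaced", t = t2, track_id = tr_a)
        g$nodes$track_id[sel_n] <- NA_integer_
        g$edges$track_id[sel_e] <- NA_integer_
      }
      bn <- !is.na(g$nodes$track_id) & g$nodes$track_id == tr_b &
        g$nodes$time_step >= t2
      be <- !is.na(g$edges$track_id) & g$edges$track_id == tr_b &
        g$edges$time_step >= t2
      g$nodes$track_id[bn] <- tr_a
      g$edges$track_id[be] <- tr_a
      g
    },
    stop("unknown edit op: ", cmd$op)
  )
}

#' Read an edit script (YAML or JSON)
#'
#' The file holds a list of edit commands in [apply_edit()]'s format, applied
#' in order by [reconstruct_axon()] or the command-line `edit` subcommand.
#'
#' @param path `.yaml`/`.yml`/`.json` file.
#' @return list of command lists.
#' @export
read_edits <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Reconstruct one axon across all time steps
#'
#' The semi-automatic loop, headless: at each frame, tips listed in the seed
#' table for that frame are added (these stand in for the interactive
#' clicks on newly emerging filopodia), then everything is propagated to the
#' next frame. Propagated filopodia keep their track IDs; seeded ones get
#' fresh tracks.
#'
#' @param prep one axon's entry from [run_preprocess()] (cropped series,
#'   trees, root-annotated graph).
#' @param tip_seeds data frame `track_id, t, x, y, z` (world um); `track_id`
#'   here is the annotation's own label, echoed in the returned mapping.
#' @param params a [filo_params()].
#' @param edits optional list of edit commands applied after the frame loop.
#' @return list with `graph` and `seed_tracks` (data frame mapping each seed
#'   row's `track_id` label to the `track_id` allocated in the graph).
#' @export
reconstruct_axon <- function(prep, tip_seeds, params = filo_params(),
                             edits = NULL) {
  g <- prep$graph
  tn <- length(prep$series$frames)
  map <- data.frame(seed_label = integer(), track_id = integer())
  for (t in seq_len(tn) - 1L) {
    rows <- which(tip_seeds$t == t)
    for (r in rows) {
      res <- add_filopodium(g, t, c(tip_seeds$x[r], tip_seeds$y[r],
                                    tip_seeds$z[r]),
                            prep$series$frames[[t + 1]], prep$trees[[t + 1]],
                            params, prep$axon_id)
      g <- res$graph
      map <- rbind(map, data.frame(seed_label = tip_seeds$track_id[r],
                                   track_id = res$track_id))
    }
    if (t < tn - 1)
      g <- propagate_filopodia(g, t, prep$series, prep$trees, params,
                               prep$axon_id)
  }
  if (!is.null(edits))
    for (cmd in edits)
      g <- apply_edit(g, cmd, prep$series, prep$trees, params, prep$axon_id)
  list(graph = g, seed_tracks = map)
}
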