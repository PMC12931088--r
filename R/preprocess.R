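# Per-dataset preparation: propagate the manually seeded terminal centers
# across all frames, derive one fixed-size crop box per axon anchored to the
# root, crop the series, and precompute the shortest-path trees.

#' Propagate the root node to the next time step
#'
#' Matches the terminal neighborhood of frame `t` in frame `t+1` with NCC
#' template matching (root template/search sizes). When the best score stays
#' below `root_gamma` the previous position is kept and a `low_ncc_root`
#' event is logged, signaling that base positions around that frame deserve
#' close proofreading.
#'
#' @param series a [time_series()] (uncropped).
#' @param graph [skeleton_graph()] holding the root at `t`.
#' @param t time step to propagate from.
#' @param params a [filo_params()].
#' @param axon_id axon terminal ID.
#' @return updated graph with a root node at `t+1`.
#' @export
propagate_root <- function(series, graph, t, params = filo_params(),
                           axon_id = 1L) {
  if (t + 1 > length(series$frames) - 1) stop("no frame at t = ", t + 1)
  rid <- root_id(graph, axon_id, t)
  if (is.na(rid)) stop("no root for axon ", axon_id, " at t = ", t)
  f0 <- series$frames[[t + 1]]; f1 <- series$frames[[t + 2]]
  v0 <- world_to_voxel(f0, node_pos(graph, rid))
  m <- match_template(f0, f1, v0, params$root_template, params$root_search,
                      params$root_gamma)
  if (m$accepted) {
    pos <- voxel_to_world(f1, m$best_position)
  } else {
    pos <- node_pos(graph, rid)
    log_event("low_ncc_root", t = t + 1, axon_id = axon_id, ncc = m$best_ncc)
  }
  add_root(graph, axon_id, t + 1, pos)
}

# 26-connected components of a logical mask; returns integer labels (0 = bg)
label_components_ <- function(mask, dims) {
  labels <- integer(length(mask))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  fg <- which(mask)
  lab <- 0L
  for (s in fg) {
    if (labels[s] != 0L) next
    lab <- lab + 1L
    labels[s] <- lab
    frontier <- s
    while (length(frontier)) {
      i <- frontier - 1L
      x <- i %% nx + 1L; y <- (i %/% nx) %% ny + 1L; z <- i %/% (nx * ny) + 1L
      cx <- rep(x, each = nrow(offs)) + offs[, 1]
      cy <- rep(y, each = nrow(offs)) + offs[, 2]
      cz <- rep(z, each = nrow(offs)) + offs[, 3]
      ok <- cx >= 1 & cx <= nx & cy >= 1 & cy <= ny & cz >= 1 & cz <= nz
      cand <- unique((cx[ok] - 1L) + nx * (cy[ok] - 1L) + nx * ny * (cz[ok] - 1L) + 1L)
      cand <- cand[mask[cand] & labels[cand] == 0L]
      labels[cand] <- lab
      frontier <- cand
    }
  }
  labels
}

# labels adjacent (within 1-voxel dilation) to the given component
adjacent_labels_ <- function(labels, dims, comp_lab) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  idx <- which(labels == comp_lab) - 1L
  x <- idx %% nx + 1L; y <- (idx %/% nx) %% ny + 1L; z <- idx %/% (nx * ny) + 1L
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  out <- integer()
  for (r in seq_len(nrow(offs))) {
    cx <- x + offs[r, 1]; cy <- y + offs[r, 2]; cz <- z + offs[r, 3]
    ok <- cx >= 1 & cx <= nx & cy >= 1 & cy <= ny & cz >= 1 & cz <= nz
    li <- labels[(cx[ok] - 1L) + nx * (cy[ok] - 1L) + nx * ny * (cz[ok] - 1L) + 1L]
    out <- unique(c(out, li[li != 0L & li != comp_lab]))
  }
  out
}

#' Estimate the crop box around an axon terminal
#'
#' Segments the bright structures with a persistence-filtered connected
#' component analysis: threshold at `theta`, 26-connected components, then
#' components whose intensity peak rises less than `persistence` above
#' `theta` are merged into the brightest component within a 1-voxel dilation
#' (plain connected components cannot separate touching terminals; the
#' persistence criterion can). The component containing the root is selected
#' and its minimal bounding box, padded by `n_margin` voxels, is returned.
#'
#' @param image a [grid_image()].
#' @param root_world root position (um).
#' @param params a [filo_params()] (uses `theta`, `persistence`, `n_margin`).
#' @return a [box3d()]; attribute `flagged` is TRUE when the root sat in
#'   background (template-sized default box) or the whole lattice was
#'   foreground.
#' @export
estimate_crop_box <- function(image, root_world, params = filo_params()) {
  d <- dim(image$values)
  rv <- world_to_voxel(image, root_world)
  mask <- image$values >= params$theta
  if (all(mask)) {
    log_event("degenerate_box", t = image$time_index)
    return(structure(box3d(c(1, 1, 1), d), flagged = TRUE))
  }
  labels <- label_components_(mask, d)
  rlin <- linear_index(rv, d)
  if (labels[rlin] == 0L) {
    log_event("root_in_background", t = image$time_index)
    half <- params$root_template %/% 2
    return(structure(clip_box(box3d(rv - half, rv + half), d), flagged = TRUE))
  }
  # persistence filter: merge weak components into their brightest neighbor
  nlab <- max(labels)
  peaks <- vapply(seq_len(nlab), function(l) max(image$values[labels == l]),
                  numeric(1))
  repeat {
    merged <- FALSE
    for (l in seq_len(nlab)) {
      if (!any(labels == l)) next
      if (peaks[l] - params$theta >= params$persistence) next
      adj <- adjacent_labels_(labels, d, l)
      adj <- adj[peaks[adj] > peaks[l]]
      if (!length(adj)) next
      target <- adj[which.max(peaks[adj])]
      labels[labels == l] <- target
      peaks[target] <- max(peaks[target], peaks[l])
      merged <- TRUE
    }
    if (!merged) break
  }
  comp <- labels == labels[rlin]
  idx <- which(comp) - 1L
  x <- idx %% d[1] + 1L; y <- (idx %/% d[1]) %% d[2] + 1L
  z <- idx %/% (d[1] * d[2]) + 1L
  structure(clip_box(box3d(c(min(x), min(y), min(z)) - params$n_margin,
                           c(max(x), max(y), max(z)) + params$n_margin), d),
            flagged = FALSE)
}

#' Preprocess a dataset: roots, crop boxes, cropped frames, Dijkstra trees
#'
#' For each seeded axon: the root is propagated across all frames, a single
#' crop-box size is derived as the union over time of the per-frame component
#' boxes re-anchored to the root, every frame is cropped with the box origin
#' following the root (so the terminal sits at a fixed voxel position in the
#' cropped series and drift is compensated), and a shortest-path tree rooted
#' at the terminal center is computed per cropped frame.
#'
#' @param series a [time_series()] (uncropped).
#' @param root_seeds data frame with columns `axon_id, t, x, y, z`
#'   (world um); one row per axon at `t = 0`.
#' @param params a [filo_params()].
#' @param out_dir optional directory; per axon writes cropped frames
#'   (`axon<k>/frame_t*.tif`), tree sidecars (`tree_t*.rds`) and the
#'   root-annotated graph (`graph.json`).
#' @return list (one entry per axon) of lists with `axon_id`, `series`
#'   (cropped [time_series()]), `trees`, `graph` (roots only), `root_voxel`
#'   (frames x 3, in cropped coordinates; constant unless the box had to be
#'   clipped at the lattice border), `box_size`.
#' @export
run_preprocess <- function(series, root_seeds, params = filo_params(),
                           out_dir = NULL) {
  stopifnot(all(c("axon_id", "t", "x", "y", "z") %in% names(root_seeds)))
  seeds0 <- root_seeds[root_seeds$t == 0, ]
  if (nrow(seeds0) == 0) stop("need a root seed at t = 0 per axon")
  tn <- length(series$frames)
  d <- dim(series$frames[[1]]$values)
  out <- list()

  for (a in seq_len(nrow(seeds0))) {
    ax <- as.integer(seeds0$axon_id[a])
    g <- skeleton_graph()
    g <- add_root(g, ax, 0L, c(seeds0$x[a], seeds0$y[a], seeds0$z[a]))
    if (tn > 1) for (t in 0:(tn - 2))
      g <- propagate_root(series, g, t, params, ax)
    root_world <- t(vapply(0:(tn - 1), function(t)
      node_pos(g, root_id(g, ax, t)), numeric(3)))
    root_vox <- t(vapply(seq_len(tn), function(i)
      world_to_voxel(series$frames[[i]], root_world[i, ]), integer(3)))

    # fixed box size: union of per-frame boxes re-anchored on the root
    off_lo <- c(Inf, Inf, Inf); off_hi <- -c(Inf, Inf, Inf)
    for (i in seq_len(tn)) {
      bx <- estimate_crop_box(series$frames[[i]], root_world[i, ], params)
      off_lo <- pmin(off_lo, bx$lo - root_vox[i, ])
      off_hi <- pmax(off_hi, bx$hi - root_vox[i, ])
    }
    size <- pmin(as.integer(off_hi - off_lo + 1), d)

    frames <- vector("list", tn); trees <- vector("list", tn)
    rvc <- matrix(NA_integer_, tn, 3)
    for (i in seq_len(tn)) {
      lo <- root_vox[i, ] + as.integer(off_lo)
      lo2 <- pmax(1L, pmin(lo, d - size + 1L))
      if (any(lo2 != lo))
        log_event("box_clipped", t = i - 1L, axon_id = ax)
      box <- box3d(lo2, lo2 + size - 1L)
      frames[[i]] <- crop(series$frames[[i]], box)
      rvc[i, ] <- root_vox[i, ] - lo2 + 1L
      trees[[i]] <- build_tree(frames[[i]], rvc[i, ], params)
    }
    cropped <- time_series(frames, series$dt)

    if (!is.null(out_dir)) {
      adir <- file.path(out_dir, paste0("axon", ax))
      dir.create(adir, showWarnings = FALSE, recursive = TRUE)
      write_series(cropped, adir)
      for (i in seq_len(tn))
        save_tree(trees[[i]], file.path(adir, sprintf("tree_t%03d.rds", i - 1L)))
      write_graph(g, file.path(adir, "graph.json"))
      jsonlite::write_json(list(axon_id = ax,
                                spacing = series$frames[[1]]$spacing,
                                dt = series$dt,
                                box_size = size,
                                origins = lapply(frames, function(f) f$origin),
                                root_voxel = rvc),
                           file.path(adir, "meta.json"),
                           digits = NA, auto_unbox = TRUE)
    }
    out[[length(out) + 1L]] <- list(axon_id = ax, series = cropped,
                                    trees = trees, graph = g,
                                    root_voxel = rvc, box_size = size)
  }
  out
}

#' Reload a preprocessed axon dataset from disk
#'
#' Restores what [run_preprocess()] wrote for one axon: the cropped frames
#' (with their per-frame origins, so world geometry is preserved), the
#' shortest-path-tree sidecars, the root-annotated graph and the metadata.
#'
#' @param dir an `axon<k>` directory written by [run_preprocess()].
#' @return the same structure as one entry of [run_preprocess()]'s result.
#' @export
read_prep <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("no meta.json in ", dir)
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  series <- load_series(dir, spacing = as.numeric(meta$spacing),
                        dt = as.numeric(meta$dt))
  orig <- meta$origins
  if (is.matrix(orig)) orig <- lapply(seq_len(nrow(orig)), function(i) orig[i, ])
  for (i in seq_along(series$frames))
    series$frames[[i]]$origin <- as.numeric(orig[[i]])
  tree_files <- sort(list.files(dir, pattern = "^tree_t\\d+\\.rds$",
                                full.names = TRUE))
  trees <- lapply(tree_files, load_tree)
  list(axon_id = as.integer(meta$axon_id), series = series, trees = trees,
       graph = read_graph(file.path(dir, "graph.json")),
       root_voxel = matrix(as.integer(meta$root_voxel), ncol = 3),
       box_size = as.integer(meta$box_size))
}
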