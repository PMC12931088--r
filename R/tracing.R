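#' Tracing edge weight between neighboring voxels
#'
#' The weight of a lattice edge combines the Euclidean step length (world
#' micrometers, so anisotropy is respected) with a penalty for dark voxels:
#' \deqn{w_{ij} = \|p_i - p_j\| + \frac{2c}{I'_i + I'_j}, \qquad
#'       I'_k = \min(\max(I_k, 1), I_{max})}
#' The cap at `i_max` keeps very bright voxels from rewarding long detours;
#' the lower clamp at 1 keeps weights finite on zero-intensity voxels while
#' still penalizing them maximally.
#'
#' @param p_i,p_j world positions (um) of the voxel centers; must be
#'   26-neighbors on the lattice.
#' @param i_i,i_j intensities in `[0, 255]`.
#' @param params a [filo_params()] (uses `c`, `i_max`).
#' @param spacing voxel spacing, used only to verify neighborhood.
#' @return positive scalar weight.
#' @export
edge_weight <- function(p_i, p_j, i_i, i_j, params = filo_params(),
                        spacing = c(0.1, 0.1, 0.5)) {
  dv <- round((p_i - p_j) / spacing)
  if (any(abs(dv) > 1) || all(dv == 0))
    stop("voxels are not 26-neighbors")
  clamp <- function(I) min(max(I, 1), params$i_max)
  sqrt(sum((p_i - p_j)^2)) + 2 * params$c / (clamp(i_i) + clamp(i_j))
}

#' Shortest-path tree from every voxel to the axon terminal center
#'
#' Runs single-source Dijkstra from the root voxel over the 26-connected
#' lattice under the intensity-weighted metric of [edge_weight()]. The tree is
#' encoded by storing, for every voxel, its neighbor next on the minimal-cost
#' path to the root, so any tip-to-root trace is a simple chain walk. Trees
#' are precomputed once per cropped frame and reused for every filopodium.
#'
#' @param image a [grid_image()].
#' @param root_voxel 1-based voxel index (length 3) of the terminal center.
#' @param params a [filo_params()].
#' @param box optional [box3d()] restricting the search; voxels outside keep
#'   infinite cost.
#' @return object of class `shortest_path_tree` with fields `pred` (linear
#'   1-based predecessor indices, 0 at the root, NA outside `box`), `cost`,
#'   `root_voxel`, `dims`, `spacing`, `origin`, `time_index`.
#' @export
build_tree <- function(image, root_voxel, params = filo_params(), box = NULL) {
  d <- dim(image$values)
  root_voxel <- as.integer(root_voxel)
  if (any(root_voxel < 1) || any(root_voxel > d))
    stop("root voxel outside lattice")
  if (is.null(box)) box <- box3d(c(1, 1, 1), d)
  res <- dijkstra_tree_cpp(as.numeric(image$values), as.integer(d),
                           image$spacing, linear_index(root_voxel, d),
                           params$c, params$i_max,
                           box$lo, box$hi)
  structure(list(pred = res$pred, cost = res$cost, root_voxel = root_voxel,
                 dims = d, spacing = image$spacing, origin = image$origin,
                 time_index = image$time_index),
            class = "shortest_path_tree")
}

linear_index <- function(v, dims) {
  as.integer(v[1] + dims[1] * (v[2] - 1) + dims[1] * dims[2] * (v[3] - 1))
}

vector_index <- function(i, dims) {
  i <- i - 1L
  c(i %% dims[1], (i %/% dims[1]) %% dims[2], i %/% (dims[1] * dims[2])) + 1L
}

#' Persist / restore a precomputed shortest-path tree
#'
#' Written as a compact binary sidecar next to the cropped frame it belongs
#' to, so repeated reconstruction sessions skip the Dijkstra pass.
#'
#' @param tree a `shortest_path_tree`.
#' @param path sidecar file (`.rds`).
#' @export
save_tree <- function(tree, path) {
  saveRDS(tree, path)
  invisible(path)
}

#' @rdname save_tree
#' @export
load_tree <- function(path) {
  tree <- readRDS(path)
  stopifnot(inherits(tree, "shortest_path_tree"))
  tree
}

#' Trace from a voxel to the root along a shortest-path tree
#'
#' Iteratively moves to the stored neighbor next on the minimal-cost path
#' until the root is reached.
#'
#' @param tree a `shortest_path_tree` from [build_tree()].
#' @param start_voxel 1-based voxel index (length 3).
#' @return polyline matrix (n x 3, world um); first row the start voxel
#'   center, last row the root voxel center.
#' @export
trace_to_root <- function(tree, start_voxel) {
  d <- tree$dims
  i <- linear_index(as.integer(start_voxel), d)
  if (any(start_voxel < 1) || any(start_voxel > d))
    stop("start voxel outside lattice")
  if (is.na(tree$pred[i])) stop("start voxel outside the tree's search box")
  path <- integer(0)
  nmax <- length(tree$pred)
  for (step in seq_len(nmax + 1L)) {
    path <- c(path, i)
    p <- tree$pred[i]
    if (p == 0L) break
    i <- p
    if (step > nmax) stop("corrupt predecessor chain (cycle)")
  }
  vox <- t(vapply(path, vector_index, integer(3), dims = d))
  sweep((vox - 1) * rep(tree$spacing, each = nrow(vox)), 2, tree$origin, "+")
}

#' Minimal-weight path between two voxels
#'
#' For pairwise traces (e.g. path corrections through a supporting point) the
#' Dijkstra run is generated on the fly, restricted to the axis-aligned
#' bounding box of the two endpoints dilated by `n_margin` voxels per
#' dimension (clipped to the lattice) — large enough to contain shortest
#' paths that bow outside the tight box.
#'
#' @param image a [grid_image()].
#' @param v_a,v_b 1-based voxel indices.
#' @param params a [filo_params()] (uses `c`, `i_max`, `n_margin`).
#' @return polyline matrix (world um) from `v_a` to `v_b`.
#' @export
trace_between <- function(image, v_a, v_b, params = filo_params()) {
  d <- dim(image$values)
  v_a <- as.integer(v_a); v_b <- as.integer(v_b)
  if (all(v_a == v_b))
    return(matrix(voxel_to_world(image, v_a), ncol = 3))
  box <- clip_box(box3d(pmin(v_a, v_b) - params$n_margin,
                        pmax(v_a, v_b) + params$n_margin), d)
  tree <- build_tree(image, v_b, params, box = box)
  trace_to_root(tree, v_a)
}

quantize_polyline <- function(m, spacing, origin) {
  v <- round(sweep(sweep(m, 2, origin, "-"), 2, spacing, "/")) + 1
  matrix(as.integer(v), ncol = 3)
}

voxel_key <- function(v) paste(v[, 1], v[, 2], v[, 3], sep = ",")

#' Insert a traced tip-to-root path into the skeleton graph
#'
#' Performs the intersection test against the paths already present at time
#' `t`: walking from the tip, the first polyline point falling into a voxel
#' already covered by an existing path becomes a junction.
#' \itemize{
#'   \item Junction on a `"filopodium"` edge (between an existing tip and its
#'     base): the new path is a branch of that filopodium. A branching node is
#'     created, the branch is truncated there, and it joins the existing
#'     track; its length is added to that filopodium's length.
#'   \item Junction on an `"axon_terminal"` edge (between a base and the
#'     root): the new path is an independent filopodium with its own track and
#'     its own base.
#'   \item No junction: the full path is inserted (first filopodium of this
#'     time step).
#' }
#'
#' @param graph a [skeleton_graph()] already holding the root node at `t`.
#' @param polyline n x 3 matrix (world um), traced tip to root.
#' @param t time step.
#' @param axon_id axon terminal ID.
#' @param image the frame the path was traced on (provides the voxel lattice
#'   used for the intersection test).
#' @param base_index optional index into `polyline` rows marking the detected
#'   base (from [estimate_base()]); when absent the base falls back to the
#'   root-adjacent point and the insertion is flagged for proofreading.
#' @param track_id track to assign (propagation); default allocates a new one.
#' @param branch_margin junction-to-base path distance (um) below which a
#'   junction on a filopodium edge is treated as an independent filopodium
#'   emerging from (essentially) the same base site, rather than a branch of
#'   the existing one; protects crowded terminals where traces of distinct
#'   filopodia converge just outside the shared base region.
#' @return list with `graph`, `track_id`, `base_required` (flag: no reliable
#'   base was placed), `merged` (flag: integrated into an existing
#'   filopodium).
#' @export
insert_path <- function(graph, polyline, t, axon_id, image,
                        base_index = NULL, track_id = NULL,
                        branch_margin = 0.3) {
  g <- graph
  rid <- root_id(g, axon_id, t)
  if (is.na(rid)) stop("no root node for axon ", axon_id, " at t = ", t)
  polyline <- dedupe_polyline(polyline)
  n <- nrow(polyline)
  if (n < 2) stop("polyline too short to insert")

  vox_new <- quantize_polyline(polyline, image$spacing, image$origin)
  keys_new <- voxel_key(vox_new)

  ei <- which(g$edges$axon_id == axon_id & g$edges$time_step == t)
  hit_edge <- NA_integer_; hit_k <- NA_integer_; hit_row <- NA_integer_
  if (length(ei)) {
    edge_keys <- lapply(ei, function(i) {
      voxel_key(quantize_polyline(g$edges$polyline[[i]],
                                  image$spacing, image$origin))
    })
    for (k in seq_len(n)) {
      for (j in seq_along(ei)) {
        r <- match(keys_new[k], edge_keys[[j]])
        if (!is.na(r)) { hit_edge <- ei[j]; hit_k <- k; hit_row <- r; break }
      }
      if (!is.na(hit_edge)) break
    }
  }

  hit_near_base <- FALSE
  if (!is.na(hit_edge) && g$edges$label[hit_edge] == "filopodium") {
    to_type <- g$nodes$type[g$nodes$node_id == g$edges$to[hit_edge]]
    if (identical(to_type, "base")) {
      m_hit <- g$edges$polyline[[hit_edge]]
      hit_near_base <- polyline_length(
        m_hit[hit_row:nrow(m_hit), , drop = FALSE]) <= branch_margin
    }
  }

  if (!is.na(hit_edge) && g$edges$label[hit_edge] == "filopodium" &&
      !hit_near_base) {
    # branch integrated into the existing filopodium
    tr <- g$edges$track_id[hit_edge]
    if (hit_k < 2) stop("new tip coincides with an existing path")
    sp <- split_edge_(g, hit_edge, hit_row, "branching", NA_integer_)
    g <- sp$graph
    res <- add_node_(g, polyline[1, ], "tip", t, axon_id, tr)
    g <- res$graph
    branch <- rbind(polyline[seq_len(hit_k - 1), , drop = FALSE],
                    node_pos(g, sp$id))
    g <- add_edge_(g, res$id, sp$id, "filopodium", t, axon_id, branch, tr)$graph
    return(list(graph = g, track_id = tr, base_required = FALSE,
                merged = TRUE))
  }

  if (is.null(track_id)) {
    track_id <- g$next_track_id
    g$next_track_id <- g$next_track_id + 1L
  }
  track_id <- as.integer(track_id)

  end_k <- if (is.na(hit_edge)) n else hit_k
  base_required <- is.null(base_index)
  bi <- if (is.null(base_index)) end_k - 1L else as.integer(base_index)
  bi <- max(2L, min(bi, end_k))

  res <- add_node_(g, polyline[1, ], "tip", t, axon_id, track_id)
  g <- res$graph; tip_id <- res$id

  if (is.na(hit_edge)) {
    # free path down to the root node
    if (bi >= n) { bi <- n - 1L; base_required <- TRUE }
    if (bi < 2L) {
      # degenerate: tip adjacent to root, no room for a base
      g <- add_edge_(g, tip_id, rid, "filopodium", t, axon_id, polyline,
                     track_id)$graph
      return(list(graph = g, track_id = track_id, base_required = TRUE,
                  merged = FALSE))
    }
    res <- add_node_(g, polyline[bi, ], "base", t, axon_id, track_id)
    g <- res$graph; base_id <- res$id
    g <- add_edge_(g, tip_id, base_id, "filopodium", t, axon_id,
                   polyline[1:bi, , drop = FALSE], track_id)$graph
    g <- add_edge_(g, base_id, rid, "axon_terminal", t, axon_id,
                   polyline[bi:n, , drop = FALSE], track_id)$graph
  } else {
    # independent filopodium joining the terminal path of another track
    if (bi >= hit_k) {
      # base coincides with the junction: the split node IS the base
      sp <- split_edge_(g, hit_edge, hit_row, "base", track_id)
      g <- sp$graph
      seg <- rbind(polyline[seq_len(hit_k - 1), , drop = FALSE],
                   node_pos(g, sp$id))
      g <- add_edge_(g, tip_id, sp$id, "filopodium", t, axon_id, seg,
                     track_id)$graph
    } else {
      sp <- split_edge_(g, hit_edge, hit_row, "branching", NA_integer_)
      g <- sp$graph
      res <- add_node_(g, polyline[bi, ], "base", t, axon_id, track_id)
      g <- res$graph; base_id <- res$id
      g <- add_edge_(g, tip_id, base_id, "filopodium", t, axon_id,
                     polyline[1:bi, , drop = FALSE], track_id)$graph
      seg <- rbind(polyline[bi:(hit_k - 1), , drop = FALSE],
                   node_pos(g, sp$id))
      g <- add_edge_(g, base_id, sp$id, "axon_terminal", t, axon_id, seg,
                     track_id)$graph
    }
  }
  list(graph = g, track_id = track_id, base_required = base_required,
       merged = FALSE)
}
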