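#' 4D skeleton graph of an axon terminal and its filopodia
#'
#' The reconstruction result is a graph whose nodes and edges all carry a
#' time-step label, so one object represents the whole time-lapse. Node types:
#' \describe{
#'   \item{root}{axon terminal center; exactly one per axon and time step.}
#'   \item{base}{origin of a filopodium on the terminal body.}
#'   \item{branching}{junction where a traced path meets a previous path.}
#'   \item{tip}{distal end of a filopodium; degree 1.}
#' }
#' Edges store dense polylines in world micrometers and are labeled
#' `"filopodium"` (on a base-to-tip path, or distal to a base) or
#' `"axon_terminal"` (between root and base). Tips and bases of a filopodium
#' carry a track ID linking the same filopodium across time steps; within one
#' time step a track ID identifies at most one filopodium.
#'
#' Per `(axon_id, time_step)` the graph is a tree rooted at the root node.
#'
#' @return An empty `skeleton_graph`: node and edge tables plus monotone id
#'   counters. Track IDs are never reused, even after a filopodium retracts.
#' @export
skeleton_graph <- function() {
  nodes <- data.frame(node_id = integer(), x = numeric(), y = numeric(),
                      z = numeric(), type = character(),
                      time_step = integer(), axon_id = integer(),
                      track_id = integer(), stringsAsFactors = FALSE)
  edges <- data.frame(edge_id = integer(), from = integer(), to = integer(),
                      label = character(), time_step = integer(),
                      axon_id = integer(), track_id = integer(),
                      stringsAsFactors = FALSE)
  edges$polyline <- list()
  structure(list(nodes = nodes, edges = edges,
                 next_node_id = 1L, next_edge_id = 1L, next_track_id = 1L),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  nt <- if (nrow(x$nodes)) length(unique(x$nodes$time_step)) else 0
  ntr <- length(stats::na.omit(unique(x$nodes$track_id)))
  cat(sprintf("skeleton_graph: %d nodes, %d edges, %d time steps, %d tracks\n",
              nrow(x$nodes), nrow(x$edges), nt, ntr))
  invisible(x)
}

node_row <- function(g, id) g$nodes[match(id, g$nodes$node_id), ]
node_pos <- function(g, id) unlist(node_row(g, id)[, c("x", "y", "z")], use.names = FALSE)

add_node_ <- function(g, pos, type, t, axon_id, track_id = NA_integer_) {
  id <- g$next_node_id
  g$nodes <- rbind(g$nodes,
                   data.frame(node_id = id, x = pos[1], y = pos[2], z = pos[3],
                              type = type, time_step = as.integer(t),
                              axon_id = as.integer(axon_id),
                              track_id = as.integer(track_id),
                              stringsAsFactors = FALSE))
  g$next_node_id <- id + 1L
  list(graph = g, id = id)
}

add_edge_ <- function(g, from, to, label, t, axon_id, polyline,
                      track_id = NA_integer_) {
  polyline <- dedupe_polyline(polyline)
  stopifnot(nrow(polyline) >= 2)
  id <- g$next_edge_id
  row <- data.frame(edge_id = id, from = as.integer(from), to = as.integer(to),
                    label = label, time_step = as.integer(t),
                    axon_id = as.integer(axon_id),
                    track_id = as.integer(track_id), stringsAsFactors = FALSE)
  row$polyline <- list(polyline)
  g$edges <- rbind(g$edges, row)
  g$next_edge_id <- id + 1L
  list(graph = g, id = id)
}

# drop exactly-repeated consecutive points
dedupe_polyline <- function(m) {
  if (!is.matrix(m)) m <- matrix(m, ncol = 3, byrow = TRUE)
  if (nrow(m) < 2) return(m)
  keep <- c(TRUE, rowSums(abs(diff(m))) > 0)
  m[keep, , drop = FALSE]
}

polyline_length <- function(m) {
  if (nrow(m) < 2) return(0)
  sum(sqrt(rowSums(diff(m)^2)))
}

#' Add a root node (axon terminal center)
#'
#' @param graph a [skeleton_graph()].
#' @param axon_id integer axon terminal ID.
#' @param t time step.
#' @param pos world position (um).
#' @return updated graph.
#' @export
add_root <- function(graph, axon_id, t, pos) {
  ex <- graph$nodes$type == "root" & graph$nodes$axon_id == axon_id &
    graph$nodes$time_step == t
  if (any(ex)) stop("root already present for axon ", axon_id, " at t = ", t)
  add_node_(graph, pos, "root", t, axon_id)$graph
}

root_id <- function(g, axon_id, t) {
  i <- which(g$nodes$type == "root" & g$nodes$axon_id == axon_id &
               g$nodes$time_step == t)
  if (length(i) != 1) return(NA_integer_)
  g$nodes$node_id[i]
}

#' Tracks present at a time step
#'
#' @param graph a [skeleton_graph()].
#' @param t time step.
#' @param axon_id restrict to one axon (default: all).
#' @return sorted integer vector of track IDs with a tip at `t`.
#' @export
tracks_at <- function(graph, t, axon_id = NULL) {
  n <- graph$nodes
  sel <- n$type == "tip" & n$time_step == t & !is.na(n$track_id)
  if (!is.null(axon_id)) sel <- sel & n$axon_id == axon_id
  sort(unique(n$track_id[sel]))
}

track_node <- function(g, track, t, type) {
  i <- which(g$nodes$track_id == track & g$nodes$time_step == t &
               g$nodes$type == type)
  if (length(i) == 0) return(NA_integer_)
  g$nodes$node_id[i[1]]
}

#' Base-to-tip length of a filopodium
#'
#' The length is the sum of Euclidean distances between consecutive polyline
#' points over all `"filopodium"`-labeled edges of the track at time `t`.
#' When a filopodium branches between tip and base, the branch belongs to the
#' same track and its length is added.
#'
#' @param graph a [skeleton_graph()].
#' @param track_id filopodium track ID.
#' @param t time step.
#' @return length in micrometers.
#' @export
path_length <- function(graph, track_id, t) {
  e <- graph$edges
  sel <- !is.na(e$track_id) & e$track_id == track_id & e$time_step == t &
    e$label == "filopodium"
  if (!any(sel)) stop("no filopodium with track ", track_id, " at t = ", t)
  sum(vapply(e$polyline[sel], polyline_length, numeric(1)))
}

incident_edges <- function(g, node_id) {
  which(g$edges$from == node_id | g$edges$to == node_id)
}

#' Check all structural invariants of a skeleton graph
#'
#' Reports violations instead of raising, so partially built or hand-edited
#' graphs can be inspected.
#'
#' @param graph a [skeleton_graph()].
#' @return character vector of human-readable violations; empty if valid.
#' @export
validate_graph <- function(graph) {
  v <- character()
  n <- graph$nodes; e <- graph$edges
  if (anyDuplicated(n$node_id)) v <- c(v, "duplicate node ids")
  if (anyDuplicated(e$edge_id)) v <- c(v, "duplicate edge ids")
  if (!all(n$type %in% c("root", "base", "branching", "tip")))
    v <- c(v, "unknown node type")
  if (!all(e$label %in% c("axon_terminal", "filopodium")))
    v <- c(v, "unknown edge label")

  for (key in unique(paste(n$axon_id, n$time_step))) {
    ax <- as.integer(strsplit(key, " ")[[1]][1])
    tt <- as.integer(strsplit(key, " ")[[1]][2])
    ni <- n[n$axon_id == ax & n$time_step == tt, ]
    roots <- ni$node_id[ni$type == "root"]
    if (length(roots) != 1)
      v <- c(v, sprintf("axon %d t %d: %d root nodes (%s)", ax, tt,
                        length(roots), paste(roots, collapse = ",")))
    ei <- e[e$axon_id == ax & e$time_step == tt, ]
    if (any(!(ei$from %in% ni$node_id) | !(ei$to %in% ni$node_id)))
      v <- c(v, sprintf("axon %d t %d: edge endpoint in another time step", ax, tt))
    deg <- table(factor(c(ei$from, ei$to), levels = ni$node_id))
    tips <- ni$node_id[ni$type == "tip"]
    bad <- tips[deg[as.character(tips)] != 1]
    if (length(bad))
      v <- c(v, sprintf("axon %d t %d: tip nodes %s not degree 1", ax, tt,
                        paste(bad, collapse = ",")))
    # tree check: connected & acyclic over this time step's subgraph
    if (nrow(ni) > 1) {
      if (nrow(ei) != nrow(ni) - 1) {
        v <- c(v, sprintf("axon %d t %d: %d edges for %d nodes (not a tree)",
                          ax, tt, nrow(ei), nrow(ni)))
      } else {
        seen <- ni$node_id[1]; frontier <- seen
        repeat {
          nxt <- unique(c(ei$to[ei$from %in% frontier],
                          ei$from[ei$to %in% frontier]))
          nxt <- setdiff(nxt, seen)
          if (!length(nxt)) break
          seen <- c(seen, nxt); frontier <- nxt
        }
        if (length(seen) != nrow(ni))
          v <- c(v, sprintf("axon %d t %d: graph not connected", ax, tt))
      }
    }
    # one filopodium per (track, t): at most one tip-set sharing a base
    tr <- stats::na.omit(unique(ni$track_id))
    for (k in tr) {
      nb <- sum(ni$type == "base" & !is.na(ni$track_id) & ni$track_id == k)
      if (nb > 1)
        v <- c(v, sprintf("axon %d t %d: track %d has %d base nodes", ax, tt, k, nb))
    }
  }
  # polyline sanity
  for (i in seq_len(nrow(e))) {
    m <- e$polyline[[i]]
    if (nrow(m) < 2) v <- c(v, sprintf("edge %d: polyline < 2 points", e$edge_id[i]))
    else if (any(rowSums(abs(diff(m))) == 0))
      v <- c(v, sprintf("edge %d: repeated consecutive polyline points", e$edge_id[i]))
  }
  v
}

#' Write / read a skeleton graph (native JSON format)
#'
#' The native format is a JSON document with a node table and an edge table
#' whose rows carry the full polylines; the round-trip is lossless including
#' id counters, so reconstruction can be resumed from file.
#'
#' @param graph a [skeleton_graph()].
#' @param path output / input file.
#' @return `read_graph` returns the restored `skeleton_graph`.
#' @export
write_graph <- function(graph, path) {
  doc <- list(format = "filotrace-graph", version = 1L,
              next_node_id = graph$next_node_id,
              next_edge_id = graph$next_edge_id,
              next_track_id = graph$next_track_id,
              nodes = graph$nodes,
              edges = graph$edges[, setdiff(names(graph$edges), "polyline")],
              polylines = graph$edges$polyline)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(doc$format) || doc$format != "filotrace-graph")
    stop("not a filotrace graph file: ", path)
  g <- skeleton_graph()
  if (length(doc$nodes)) {
    nd <- as.data.frame(doc$nodes)
    nd$track_id <- as.integer(nd$track_id)
    g$nodes <- nd[, names(g$nodes)]
  }
  if (length(doc$edges)) {
    ed <- as.data.frame(doc$edges)
    ed$track_id <- as.integer(ed$track_id)
    pl <- doc$polylines
    if (is.matrix(pl)) pl <- list(pl)          # single-edge graph
    ed$polyline <- lapply(pl, function(m) matrix(as.numeric(m), ncol = 3))
    g$edges <- ed[, names(g$edges)]
  }
  g$next_node_id <- as.integer(doc$next_node_id)
  g$next_edge_id <- as.integer(doc$next_edge_id)
  g$next_track_id <- as.integer(doc$next_track_id)
  g
}

#' Export one time step as SWC
#'
#' SWC cannot carry time labels or track IDs, so the export covers a single
#' `(axon_id, time_step)` tree. Polyline points become intermediate samples.
#' Type codes: 1 root (soma), 5 branching (fork), 6 tip (end point), 7 base,
#' 0 intermediate polyline points.
#'
#' @param graph a [skeleton_graph()].
#' @param t time step to export.
#' @param path output `.swc` file.
#' @param axon_id axon to export.
#' @param radius constant radius written for every sample (um).
#' @export
write_swc <- function(graph, t, path, axon_id = 1L, radius = 0.1) {
  rid <- root_id(graph, axon_id, t)
  if (is.na(rid)) stop("no root for axon ", axon_id, " at t = ", t)
  type_code <- c(root = 1L, branching = 5L, tip = 6L, base = 7L)
  e <- graph$edges[graph$edges$axon_id == axon_id & graph$edges$time_step == t, ]
  n <- graph$nodes[graph$nodes$axon_id == axon_id & graph$nodes$time_step == t, ]

  samples <- data.frame(id = 1L, type = 1L,
                        x = n$x[n$node_id == rid], y = n$y[n$node_id == rid],
                        z = n$z[n$node_id == rid], parent = -1L)
  swc_of_node <- stats::setNames(1L, as.character(rid))
  nxt <- 2L

  # orient edges away from the root by BFS
  remaining <- seq_len(nrow(e))
  frontier <- rid
  while (length(remaining) && length(frontier)) {
    new_frontier <- integer()
    used <- integer()
    for (i in remaining) {
      a <- e$from[i]; b <- e$to[i]
      if (!(a %in% frontier) && !(b %in% frontier)) next
      prox <- if (a %in% frontier) a else b
      dist <- if (a %in% frontier) b else a
      m <- e$polyline[[i]]
      ppos <- n[n$node_id == prox, c("x", "y", "z")]
      if (sum((m[1, ] - unlist(ppos))^2) > sum((m[nrow(m), ] - unlist(ppos))^2))
        m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
      parent <- swc_of_node[[as.character(prox)]]
      if (nrow(m) > 2) {
        for (k in 2:(nrow(m) - 1)) {
          samples <- rbind(samples, data.frame(id = nxt, type = 0L,
                                               x = m[k, 1], y = m[k, 2],
                                               z = m[k, 3], parent = parent))
          parent <- nxt; nxt <- nxt + 1L
        }
      }
      dtype <- type_code[[n$type[n$node_id == dist]]]
      samples <- rbind(samples, data.frame(id = nxt, type = dtype,
                                           x = m[nrow(m), 1], y = m[nrow(m), 2],
                                           z = m[nrow(m), 3], parent = parent))
      swc_of_node[[as.character(dist)]] <- nxt
      nxt <- nxt + 1L
      new_frontier <- c(new_frontier, dist)
      used <- c(used, i)
    }
    remaining <- setdiff(remaining, used)
    frontier <- new_frontier
  }
  lines <- c("# SWC export (one time step); types: 1 root, 5 branching, 6 tip, 7 base, 0 path point",
             sprintf("%d %d %.6f %.6f %.6f %.6f %d", samples$id, samples$type,
                     samples$x, samples$y, samples$z, radius, samples$parent))
  writeLines(lines, path)
  invisible(path)
}

# Split an edge at polyline row `k`, inserting a node of `node_type` there.
# Returns list(graph, id of the new node). The two half-edges inherit label,
# track and time step of the original.
split_edge_ <- function(g, edge_index, k, node_type, track_id = NA_integer_) {
  e <- g$edges[edge_index, ]
  m <- e$polyline[[1]]
  stopifnot(k >= 1, k <= nrow(m))
  if (k == 1 || k == nrow(m)) {
    id <- if (k == 1) e$from else e$to
    return(list(graph = g, id = id, split = FALSE))
  }
  res <- add_node_(g, m[k, ], node_type, e$time_step, e$axon_id, track_id)
  g <- res$graph; nid <- res$id
  g$edges <- g$edges[-edge_index, ]
  r1 <- add_edge_(g, e$from, nid, e$label, e$time_step, e$axon_id,
                  m[1:k, , drop = FALSE], e$track_id)
  g <- r1$graph
  r2 <- add_edge_(g, nid, e$to, e$label, e$time_step, e$axon_id,
                  m[k:nrow(m), , drop = FALSE], e$track_id)
  list(graph = r2$graph, id = nid, split = TRUE)
}

# Merge the two edges incident to a degree-2 node (same label/track) and drop
# the node; used when deleting filopodia leaves an obsolete branching node.
heal_node_ <- function(g, node_id) {
  ii <- incident_edges(g, node_id)
  if (length(ii) != 2) return(g)
  e1 <- g$edges[ii[1], ]; e2 <- g$edges[ii[2], ]
  if (e1$label != e2$label || !identical(e1$track_id, e2$track_id)) return(g)
  m1 <- e1$polyline[[1]]; m2 <- e2$polyline[[1]]
  pos <- node_pos(g, node_id)
  if (sum((m1[nrow(m1), ] - pos)^2) > 1e-18) m1 <- m1[rev(seq_len(nrow(m1))), ]
  if (sum((m2[1, ] - pos)^2) > 1e-18) m2 <- m2[rev(seq_len(nrow(m2))), ]
  a <- if (isTRUE(all.equal(unname(e1$from), unname(node_id)))) e1$to else e1$from
  b <- if (isTRUE(all.equal(unname(e2$from), unname(node_id)))) e2$to else e2$from
  g$edges <- g$edges[-ii, ]
  g <- add_edge_(g, a, b, e1$label, e1$time_step, e1$axon_id,
                 rbind(m1, m2[-1, , drop = FALSE]), e1$track_id)$graph
  g$nodes <- g$nodes[g$nodes$node_id != node_id, ]
  g
}

#' Delete a filopodium from one time step
#'
#' Removes the track's tip, its filopodium edges, and its base together with
#' the base-to-root connection when no other filopodium shares them; obsolete
#' degree-2 branching nodes are healed. Nodes of the same track at other time
#' steps are untouched.
#'
#' @param graph a [skeleton_graph()].
#' @param t time step.
#' @param track_id track to remove.
#' @return updated graph.
#' @export
delete_filopodium <- function(graph, t, track_id) {
  g <- graph
  sel <- !is.na(g$edges$track_id) & g$edges$track_id == track_id &
    g$edges$time_step == t & g$edges$label == "filopodium"
  if (!any(sel) ) stop("no filopodium with track ", track_id, " at t = ", t)
  touched <- unique(c(g$edges$from[sel], g$edges$to[sel]))
  g$edges <- g$edges[!sel, ]
  nsel <- g$nodes$node_id %in% touched & g$nodes$time_step == t &
    g$nodes$type %in% c("tip", "base", "branching")
  for (id in g$nodes$node_id[nsel]) {
    deg <- length(incident_edges(g, id))
    ty <- g$nodes$type[g$nodes$node_id == id]
    if (deg == 0) {
      g$nodes <- g$nodes[g$nodes$node_id != id, ]
    } else if (ty == "base" && deg == 1) {
      # base only held this filopodium: drop it and its terminal connection
      ii <- incident_edges(g, id)
      other <- setdiff(c(g$edges$from[ii], g$edges$to[ii]), id)
      g$edges <- g$edges[-ii, ]
      g$nodes <- g$nodes[g$nodes$node_id != id, ]
      for (o in other)
        if (g$nodes$type[g$nodes$node_id == o] == "branching")
          g <- heal_node_(g, o)
    } else if (ty == "branching" && deg == 2) {
      g <- heal_node_(g, id)
    }
  }
  g
}
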