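# Per-filopodium dynamics statistics computed from the final 4D skeleton
# graph, and their spreadsheet export.

#' Count extension and retraction events from a length trajectory
#'
#' A step counts as an extension when the filopodium is strictly longer than
#' in the previous time step, as a retraction when strictly shorter; equal
#' lengths count as neither (reported separately as ties), so
#' `n_extensions + n_retractions + n_ties = steps - 1` always holds.
#'
#' @param lengths per-time-step lengths (um) of one filopodium.
#' @return named integer vector `c(n_extensions, n_retractions, n_ties)`.
#' @export
count_events <- function(lengths) {
  stopifnot(length(lengths) >= 1)
  d <- diff(lengths)
  c(n_extensions = sum(d > 0), n_retractions = sum(d < 0), n_ties = sum(d == 0))
}

#' Mean extension and retraction velocities
#'
#' Means are taken over event steps only: the extension velocity averages the
#' positive length changes per minute over extension steps (0 when there are
#' none), the retraction velocity averages the absolute changes over
#' retraction steps.
#'
#' @param lengths per-time-step lengths (um).
#' @param dt minutes between time steps.
#' @return named numeric `c(mean_ext_velocity, mean_ret_velocity)` in um/min.
#' @export
velocities <- function(lengths, dt) {
  d <- diff(lengths)
  c(mean_ext_velocity = if (any(d > 0)) mean(d[d > 0]) / dt else 0,
    mean_ret_velocity = if (any(d < 0)) mean(abs(d[d < 0])) / dt else 0)
}

#' Growth angle of a filopodium
#'
#' Angle between the root-to-base vector, projected onto the x-y plane, and
#' the unit vector (0, 1):
#' \deqn{\cos\alpha = \frac{\langle v, e_2 \rangle}{|v||e_2|}}
#' Evaluated at the filopodium's first time step, it describes where around
#' the terminal the filopodium formed. Returned in degrees in `[0, 180]`
#' (the arccos is unsigned). Invariant to translations and to any change in
#' z.
#'
#' @param root_pos,base_pos world positions (um), length >= 2 (only x, y
#'   used).
#' @return angle in degrees, or `NA` (with a warning) if root and base
#'   coincide after projection.
#' @export
growth_angle <- function(root_pos, base_pos) {
  v <- base_pos[1:2] - root_pos[1:2]
  nv <- sqrt(sum(v^2))
  if (nv == 0) {
    warning("root and base coincide in the x-y projection; angle undefined")
    return(NA_real_)
  }
  acos(pmin(pmax(v[2] / nv, -1), 1)) * 180 / pi
}

#' Per-track dynamics summary of a skeleton graph
#'
#' @param graph a reconstructed [skeleton_graph()].
#' @param dt minutes between time steps.
#' @return list of two data frames:
#'   \describe{
#'     \item{lengths}{long format, one row per (track, time step):
#'       `track_id, time_step, length_um`.}
#'     \item{summary}{one row per track: `track_id, birth, death,
#'       lifetime_min, mean_length_um, n_extensions, n_retractions, n_ties,
#'       mean_ext_velocity, mean_ret_velocity, growth_angle_deg`.}
#'   }
#' @export
filopodia_stats <- function(graph, dt = 1) {
  lengths <- data.frame(track_id = integer(), time_step = integer(),
                        length_um = numeric())
  summary <- data.frame(track_id = integer(), birth = integer(),
                        death = integer(), lifetime_min = numeric(),
                        mean_length_um = numeric(), n_extensions = integer(),
                        n_retractions = integer(), n_ties = integer(),
                        mean_ext_velocity = numeric(),
                        mean_ret_velocity = numeric(),
                        growth_angle_deg = numeric())
  n <- graph$nodes
  tracks <- sort(stats::na.omit(unique(n$track_id[n$type == "tip"])))
  for (tr in tracks) {
    steps <- sort(unique(n$time_step[n$type == "tip" & !is.na(n$track_id) &
                                       n$track_id == tr]))
    L <- vapply(steps, function(t) path_length(graph, tr, t), numeric(1))
    lengths <- rbind(lengths, data.frame(track_id = tr, time_step = steps,
                                         length_um = L))
    ev <- count_events(L)
    vel <- velocities(L, dt)
    t0 <- steps[1]
    base0 <- track_node(graph, tr, t0, "base")
    ax <- n$axon_id[n$type == "tip" & !is.na(n$track_id) & n$track_id == tr][1]
    r0 <- root_id(graph, ax, t0)
    ang <- if (!is.na(base0) && !is.na(r0))
      growth_angle(node_pos(graph, r0), node_pos(graph, base0))
    else NA_real_
    summary <- rbind(summary, data.frame(
      track_id = tr, birth = t0, death = steps[length(steps)],
      lifetime_min = (steps[length(steps)] - t0 + 1) * dt,
      mean_length_um = mean(L),
      n_extensions = as.integer(ev["n_extensions"]),
      n_retractions = as.integer(ev["n_retractions"]),
      n_ties = as.integer(ev["n_ties"]),
      mean_ext_velocity = as.numeric(vel["mean_ext_velocity"]),
      mean_ret_velocity = as.numeric(vel["mean_ret_velocity"]),
      growth_angle_deg = ang))
  }
  list(lengths = lengths, summary = summary)
}

#' Export the statistics spreadsheets
#'
#' Writes `filopodia_lengths.csv` (per track and time step) and
#' `filopodia_summary.csv` (per track) with one header row each. Output is
#' deterministic: re-exporting the same graph is byte-identical.
#'
#' @param graph a [skeleton_graph()].
#' @param dt minutes between time steps.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the two file paths.
#' @export
export_tables <- function(graph, dt, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- filopodia_stats(graph, dt)
  p1 <- file.path(out_dir, "filopodia_lengths.csv")
  p2 <- file.path(out_dir, "filopodia_summary.csv")
  utils::write.csv(format(st$lengths, digits = 12, trim = TRUE,
                          scientific = FALSE),
                   p1, row.names = FALSE, quote = FALSE)
  utils::write.csv(format(st$summary, digits = 12, trim = TRUE,
                          scientific = FALSE),
                   p2, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}
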