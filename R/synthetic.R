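# Ground-truthed synthetic two-photon time series.
#
# Emulates the imaging characteristics of the real data: a bright compact
# axon terminal (uniform-core ellipsoid with a Gaussian edge), thin tube-like
# filopodia with Gaussian transverse intensity profiles, anisotropic axial
# blur (tube/blob kernels are wider along z than in x-y), additive Gaussian
# and optional shot noise, slow whole-terminal drift, and per-filopodium
# extension/retraction/birth/death dynamics. Every frame comes with the true
# skeleton (root, bases, tips, centerline polylines, track IDs), so tracing,
# base detection and tracking can be scored against ground truth.

#' Configuration for the synthetic series generator
#'
#' Defaults describe a desk-scale axon terminal movie matching the real
#' acquisition geometry: 0.1 x 0.1 x 0.5 um voxels, 1 min between frames,
#' 8-bit intensities, terminal drift well inside the root search window and
#' tip motion inside the tip search window.
#'
#' @param dims lattice size in voxels (x, y, z).
#' @param spacing voxel spacing (um).
#' @param n_frames number of time steps.
#' @param dt minutes between frames.
#' @param blob_center world position (um) of the terminal center at t = 0.
#' @param blob_radius ellipsoid semi-axes (um) of the terminal body.
#' @param blob_peak core intensity of the terminal body.
#' @param blob_edge edge softness (normalized radius units).
#' @param n_filopodia number of filopodia.
#' @param birth,death integer vectors (length `n_filopodia`) of first/last
#'   frames each filopodium exists; `NULL` draws a default pattern (most
#'   born at t = 0, some later; a few die early).
#' @param length0 range (um) of initial lengths.
#' @param walk_sd per-frame standard deviation (um) of the bounded random
#'   walk on length.
#' @param length_bounds reflecting bounds (um) on length; the lower bound is
#'   deliberately below the `l_min` retraction threshold so shrink-below-
#'   threshold events occur.
#' @param length_traj optional list of per-filopodium length trajectories
#'   (numeric vectors of length `n_frames`, NA outside the live interval);
#'   overrides the random walk, e.g. to program a deterministic shrink below
#'   the retraction threshold.
#' @param tube_sigma_xy transverse Gaussian sigma of a filopodium tube (um).
#' @param tube_sigma_z axial sigma (um); larger than `tube_sigma_xy`, which
#'   realizes the anisotropic axial blur of two-photon stacks.
#' @param tube_peak centerline intensity of a tube.
#' @param curvature_sd per-filopodium in-plane curvature (rad/um) sd.
#' @param z_slope_max maximal |z| component of a filopodium direction.
#' @param drift world drift velocity (um/frame) of the whole terminal.
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param poisson also apply shot noise (Poisson with the voxel's intensity
#'   as mean)?
#' @param seed RNG seed; a fixed seed makes the series and truth bit-identical
#'   across runs.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(dims = c(110L, 100L, 16L),
                       spacing = c(0.1, 0.1, 0.5),
                       n_frames = 20L, dt = 1,
                       blob_center = c(5.0, 5.0, 3.5),
                       blob_radius = c(0.8, 0.8, 1.0),
                       blob_peak = 200, blob_edge = 0.18,
                       n_filopodia = 10L,
                       birth = NULL, death = NULL,
                       length0 = c(1.0, 2.5),
                       walk_sd = 0.15,
                       length_bounds = c(0.25, 3.0),
                       length_traj = NULL,
                       tube_sigma_xy = 0.13, tube_sigma_z = 0.4,
                       tube_peak = 180,
                       curvature_sd = 0.15, z_slope_max = 0.15,
                       drift = c(0.1, -0.05, 0),
                       noise_sd = 5, poisson = FALSE,
                       seed = 42L) {
  cfg <- as.list(environment())
  cfg$dims <- as.integer(dims)
  cfg$n_frames <- as.integer(n_frames)
  cfg$n_filopodia <- as.integer(n_filopodia)
  stopifnot(cfg$n_frames >= 1, cfg$n_filopodia >= 0, all(cfg$dims > 1),
            length_bounds[1] > 0, length_bounds[2] > length_bounds[1])
  class(cfg) <- "sim_config"
  cfg
}

# deterministic default birth/death pattern
default_schedule <- function(cfg) {
  n <- cfg$n_filopodia; tmax <- cfg$n_frames - 1L
  if (n == 0) return(list(birth = integer(), death = integer()))
  birth <- rep(0L, n)
  if (n > 6) birth[7:n] <- as.integer(1 + (seq_len(n - 6) * 2) %% max(tmax %/% 2, 1))
  death <- rep(tmax, n)
  if (n >= 4 && tmax >= 8) death[3] <- as.integer(tmax - 4L)  # one early death
  if (n >= 8 && tmax >= 10) death[8] <- as.integer(tmax - 2L)
  death <- pmax(death, birth + 1L)
  list(birth = birth, death = pmin(death, tmax))
}

# centerline from an anchor outward: arc-length steps with constant in-plane
# curvature and constant z slope; returns (m x 3) world points, base first
filo_centerline <- function(anchor, dir0, length, curvature, step = 0.05) {
  m <- max(2L, ceiling(length / step) + 1L)
  s <- length / (m - 1)
  pts <- matrix(0, m, 3)
  pts[1, ] <- anchor
  d <- dir0
  theta <- curvature * s
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  for (k in 2:m) {
    pts[k, ] <- pts[k - 1, ] + d * s
    d[1:2] <- as.numeric(rot %*% d[1:2])
    d <- d / sqrt(sum(d^2))
  }
  pts
}

# splat max(tube) Gaussian profile around a centerline into `img`
render_tube <- function(img, dims, spacing, centerline, peak, sxy, sz) {
  rx <- ceiling(3 * sxy / spacing[1]); ry <- ceiling(3 * sxy / spacing[2])
  rz <- ceiling(3 * sz / spacing[3])
  for (k in seq_len(nrow(centerline))) {
    p <- centerline[k, ]
    v <- round(p / spacing) + 1
    xs <- max(1, v[1] - rx):min(dims[1], v[1] + rx)
    ys <- max(1, v[2] - ry):min(dims[2], v[2] + ry)
    zs <- max(1, v[3] - rz):min(dims[3], v[3] + rz)
    if (!length(xs) || !length(ys) || !length(zs)) next
    dx2 <- ((xs - 1) * spacing[1] - p[1])^2
    dy2 <- ((ys - 1) * spacing[2] - p[2])^2
    dz2 <- ((zs - 1) * spacing[3] - p[3])^2
    q <- outer(outer(dx2, dy2, "+") / sxy^2, dz2 / sz^2, "+")
    contrib <- peak * exp(-0.5 * q)
    img[xs, ys, zs] <- pmax(img[xs, ys, zs], contrib)
  }
  img
}

render_blob <- function(img, dims, spacing, center, radius, peak, edge) {
  r <- ceiling((radius * 2.5) / spacing)
  v <- round(center / spacing) + 1
  xs <- max(1, v[1] - r[1]):min(dims[1], v[1] + r[1])
  ys <- max(1, v[2] - r[2]):min(dims[2], v[2] + r[2])
  zs <- max(1, v[3] - r[3]):min(dims[3], v[3] + r[3])
  nx2 <- (((xs - 1) * spacing[1] - center[1]) / radius[1])^2
  ny2 <- (((ys - 1) * spacing[2] - center[2]) / radius[2])^2
  nz2 <- (((zs - 1) * spacing[3] - center[3]) / radius[3])^2
  dn <- sqrt(outer(outer(nx2, ny2, "+"), nz2, "+"))
  contrib <- peak * exp(-0.5 * (pmax(dn - 1, 0) / edge)^2)  # uniform core
  img[xs, ys, zs] <- pmax(img[xs, ys, zs], contrib)
  img
}

#' Simulate a ground-truthed filopodia time series
#'
#' Renders the frames described by [sim_config()] and returns them together
#' with the exact skeleton. Reproducible: a fixed seed gives bit-identical
#' output.
#'
#' @param cfg a [sim_config()].
#' @return list of class `filo_sim` with elements
#'   \describe{
#'     \item{series}{[time_series()] of rendered frames.}
#'     \item{truth}{list: `graph` (the true [skeleton_graph()], track ID k for
#'       filopodium k), `lengths` (n_filopodia x n_frames matrix of true
#'       base-to-tip lengths, NA where not alive), `tip_pos`/`base_pos`
#'       (n_filopodia x 3 x n_frames arrays, world um), `root` (n_frames x 3),
#'       `birth`, `death`, `alive` (logical matrix).}
#'     \item{config}{the config used.}
#'   }
#' @export
simulate_series <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed)

  n <- cfg$n_filopodia; tn <- cfg$n_frames
  sched <- if (is.null(cfg$birth) || is.null(cfg$death)) default_schedule(cfg)
           else list(birth = as.integer(cfg$birth), death = as.integer(cfg$death))
  birth <- sched$birth; death <- sched$death

  # static per-filopodium geometry (relative to the un-drifted terminal)
  if (n > 0) {
    phi <- 2 * pi * (seq_len(n) - 1) / max(n, 1) + stats::runif(n, -0.2, 0.2)
    zsl <- stats::runif(n, -cfg$z_slope_max, cfg$z_slope_max)
    dirs <- cbind(cos(phi) * sqrt(1 - zsl^2), sin(phi) * sqrt(1 - zsl^2), zsl)
    curv <- stats::rnorm(n, 0, cfg$curvature_sd)
    anchors <- sweep(dirs * rep(cfg$blob_radius, each = n), 2, cfg$blob_center, "+")
    len0 <- stats::runif(n, cfg$length0[1], cfg$length0[2])
  }

  # length trajectories: bounded (reflecting) random walk, unless programmed
  lengths <- matrix(NA_real_, n, tn)
  if (n > 0) for (k in seq_len(n)) {
    if (!is.null(cfg$length_traj)) {
      lengths[k, ] <- cfg$length_traj[[k]]
      next
    }
    L <- len0[k]
    for (t in seq.int(birth[k], death[k])) {
      lengths[k, t + 1] <- L
      L <- L + stats::rnorm(1, 0, cfg$walk_sd)
      if (L < cfg$length_bounds[1])
        L <- 2 * cfg$length_bounds[1] - L
      if (L > cfg$length_bounds[2])
        L <- 2 * cfg$length_bounds[2] - L
    }
  }

  g <- skeleton_graph()
  tip_pos <- array(NA_real_, c(max(n, 1), 3, tn))
  base_pos <- array(NA_real_, c(max(n, 1), 3, tn))
  root <- matrix(NA_real_, tn, 3)
  frames <- vector("list", tn)
  clipped <- FALSE
  world_max <- (cfg$dims - 1) * cfg$spacing

  for (t in seq_len(tn) - 1L) {
    shift <- cfg$drift * t
    ctr <- cfg$blob_center + shift
    root[t + 1, ] <- ctr
    g <- add_root(g, 1L, t, ctr)
    img <- array(0, dim = cfg$dims)
    img <- render_blob(img, cfg$dims, cfg$spacing, ctr, cfg$blob_radius,
                       cfg$blob_peak, cfg$blob_edge)
    if (n > 0) for (k in seq_len(n)) {
      if (t < birth[k] || t > death[k] || is.na(lengths[k, t + 1])) next
      cl <- filo_centerline(anchors[k, ] + shift, dirs[k, ], lengths[k, t + 1],
                            curv[k])
      inb <- cl[, 1] >= 0 & cl[, 1] <= world_max[1] &
             cl[, 2] >= 0 & cl[, 2] <= world_max[2] &
             cl[, 3] >= 0 & cl[, 3] <= world_max[3]
      if (!all(inb)) { clipped <- TRUE; cl <- cl[inb, , drop = FALSE] }
      if (nrow(cl) < 2) next
      img <- render_tube(img, cfg$dims, cfg$spacing, cl, cfg$tube_peak,
                         cfg$tube_sigma_xy, cfg$tube_sigma_z)
      tip <- cl[nrow(cl), ]; base <- cl[1, ]
      tip_pos[k, , t + 1] <- tip; base_pos[k, , t + 1] <- base
      rtip <- add_node_(g, tip, "tip", t, 1L, k); g <- rtip$graph
      rbase <- add_node_(g, base, "base", t, 1L, k); g <- rbase$graph
      g <- add_edge_(g, rtip$id, rbase$id, "filopodium", t, 1L,
                     cl[rev(seq_len(nrow(cl))), , drop = FALSE], k)$graph
      g <- add_edge_(g, rbase$id, root_id(g, 1L, t), "axon_terminal", t, 1L,
                     rbind(base, ctr), k)$graph
    }
    if (cfg$poisson) {
      nv <- length(img)
      img <- array(stats::rpois(nv, lambda = pmax(img, 0)), dim = cfg$dims)
    }
    if (cfg$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, cfg$noise_sd)
    img <- round(pmin(pmax(img, 0), 255))
    frames[[t + 1]] <- grid_image(img, cfg$spacing, time_index = t)
  }
  if (n > 0) g$next_track_id <- n + 1L

  structure(list(series = time_series(frames, cfg$dt),
                 truth = list(graph = g, lengths = lengths,
                              tip_pos = tip_pos, base_pos = base_pos,
                              root = root, birth = birth, death = death,
                              alive = !is.na(lengths), clipped = clipped),
                 config = cfg),
            class = "filo_sim")
}

#' Write seed files derived from simulator ground truth
#'
#' Emulates the manual annotations the workflow needs: one root click per
#' axon at t = 0 and one tip click per filopodium at its birth frame. An
#' optional jitter emulates imperfect clicks.
#'
#' @param sim a `filo_sim` from [simulate_series()].
#' @param dir output directory; writes `root_seeds.csv`
#'   (axon_id, t, x, y, z) and `tip_seeds.csv` (track_id, t, x, y, z),
#'   coordinates in world um.
#' @param jitter_um uniform jitter half-width (um) added to tip seeds in x-y.
#' @param seed RNG seed for the jitter.
#' @return list with the two data frames (also written if `dir` not NULL).
#' @export
write_seeds <- function(sim, dir = NULL, jitter_um = 0, seed = 1L) {
  roots <- data.frame(axon_id = 1L, t = 0L,
                      x = sim$truth$root[1, 1], y = sim$truth$root[1, 2],
                      z = sim$truth$root[1, 3])
  tr <- sim$truth
  n <- length(tr$birth)
  tips <- data.frame(track_id = integer(), t = integer(),
                     x = numeric(), y = numeric(), z = numeric())
  if (n > 0) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(seed)
    for (k in seq_len(n)) {
      tb <- tr$birth[k]
      p <- tr$tip_pos[k, , tb + 1]
      if (jitter_um > 0)
        p[1:2] <- p[1:2] + stats::runif(2, -jitter_um, jitter_um)
      tips <- rbind(tips, data.frame(track_id = k, t = tb,
                                     x = p[1], y = p[2], z = p[3]))
    }
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(roots, file.path(dir, "root_seeds.csv"), row.names = FALSE)
    utils::write.csv(tips, file.path(dir, "tip_seeds.csv"), row.names = FALSE)
  }
  list(root_seeds = roots, tip_seeds = tips)
}
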