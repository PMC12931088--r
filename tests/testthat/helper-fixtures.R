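# Fixtures are built in code at test time: small analytic images with known
# geometry, plus an independent plain-R Dijkstra oracle.

SPACING <- c(0.1, 0.1, 0.5)

# image whose value at voxel (x,y,z) is a unique ramp, handy for indexing checks
ramp_image <- function(dims = c(24L, 20L, 6L), spacing = SPACING) {
  vals <- array(seq_len(prod(dims)) %% 256, dim = dims)
  grid_image(vals, spacing)
}

# straight tube with Gaussian transverse profile from `from` toward `dir`
# (unit um), length L; optionally a terminal blob at `from`
tube_image <- function(dims = c(60L, 40L, 9L), spacing = SPACING,
                       from = c(1.5, 2.0, 2.0), dir = c(1, 0, 0), L = 3,
                       peak = 180, sxy = 0.13, sz = 0.4,
                       blob = NULL, noise_sd = 0, seed = 1) {
  img <- array(0, dim = dims)
  cl <- sweep(outer(seq(0, L, by = 0.05), dir / sqrt(sum(dir^2))), 2, from, "+")
  img <- filotrace:::render_tube(img, dims, spacing, cl, peak, sxy, sz)
  if (!is.null(blob))
    img <- filotrace:::render_blob(img, dims, spacing, blob$center,
                                   blob$radius, blob$peak, 0.18)
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + rnorm(length(img), 0, noise_sd)
  }
  grid_image(round(pmin(pmax(img, 0), 255)), spacing)
}

# plain-R single-source Dijkstra over the 26-neighborhood; O(n^2), for tiny
# lattices only — deliberately independent of the compiled implementation
oracle_dijkstra <- function(image, root_voxel, params = filo_params()) {
  d <- dim(image$values)
  nvox <- prod(d)
  sp <- image$spacing
  coord <- function(i) {
    i <- i - 1
    c(i %% d[1], (i %/% d[1]) %% d[2], i %/% (d[1] * d[2])) + 1
  }
  lin <- function(v) v[1] + d[1] * (v[2] - 1) + d[1] * d[2] * (v[3] - 1)
  Iv <- pmin(pmax(as.numeric(image$values), 1), params$i_max)
  dist <- rep(Inf, nvox)
  dist[lin(root_voxel)] <- 0
  done <- rep(FALSE, nvox)
  repeat {
    open <- which(!done & is.finite(dist))
    if (!length(open)) break
    u <- open[which.min(dist[open])]
    done[u] <- TRUE
    cu <- coord(u)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      cv <- cu + c(dx, dy, dz)
      if (any(cv < 1) || any(cv > d)) next
      v <- lin(cv)
      w <- sqrt(sum((c(dx, dy, dz) * sp)^2)) + 2 * params$c / (Iv[u] + Iv[v])
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  dist
}

# one-axon simulated scene, preprocessed: the work-horse for end-to-end tests
small_scene <- function(n_frames = 3, n_filopodia = 3, seed = 7, ...) {
  sim <- simulate_series(sim_config(n_frames = n_frames,
                                    n_filopodia = n_filopodia,
                                    seed = seed, ...))
  seeds <- write_seeds(sim)
  prep <- run_preprocess(sim$series, seeds$root_seeds)[[1]]
  list(sim = sim, seeds = seeds, prep = prep)
}

xy_vox_error <- function(p, q, spacing = SPACING) {
  sqrt(sum((p[1:2] - q[1:2])^2)) / spacing[1]
}
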