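# Filopodium base estimation.
#
# Along a traced tip-to-root path, the transverse intensity profile is close
# to Gaussian while inside the thin filopodium and clearly non-Gaussian
# (broad, near-uniform) once the path enters the axon terminal body. The base
# is placed at the change point of a per-point "Gaussian-ness" score: the
# RMSD between radially sampled intensities in the plane orthogonal to the
# path and an ideal isotropic Gaussian fitted to them.

# Trilinear interpolation of image intensities at world points (n x 3).
interp_trilinear <- function(image, pts) {
  d <- dim(image$values)
  u <- sweep(sweep(to_mat3(pts), 2, image$origin, "-"), 2, image$spacing, "/") + 1
  u[, 1] <- pmin(pmax(u[, 1], 1), d[1])
  u[, 2] <- pmin(pmax(u[, 2], 1), d[2])
  u[, 3] <- pmin(pmax(u[, 3], 1), d[3])
  f <- pmin(floor(u), rep(d - 1L, each = nrow(u)))
  f <- pmax(f, 1)
  w <- u - f
  v <- image$values
  gi <- function(ox, oy, oz)
    v[cbind(f[, 1] + ox, f[, 2] + oy, f[, 3] + oz)]
  (1 - w[, 1]) * (1 - w[, 2]) * (1 - w[, 3]) * gi(0, 0, 0) +
    w[, 1] * (1 - w[, 2]) * (1 - w[, 3]) * gi(1, 0, 0) +
    (1 - w[, 1]) * w[, 2] * (1 - w[, 3]) * gi(0, 1, 0) +
    w[, 1] * w[, 2] * (1 - w[, 3]) * gi(1, 1, 0) +
    (1 - w[, 1]) * (1 - w[, 2]) * w[, 3] * gi(0, 0, 1) +
    w[, 1] * (1 - w[, 2]) * w[, 3] * gi(1, 0, 1) +
    (1 - w[, 1]) * w[, 2] * w[, 3] * gi(0, 1, 1) +
    w[, 1] * w[, 2] * w[, 3] * gi(1, 1, 1)
}

#' Gaussian-ness of the transverse intensity profile at a path point
#'
#' Samples intensities by trilinear interpolation on `k_rays` rays times
#' `n_radii` evenly spaced radii (up to `r_max` um) transverse to the local
#' path tangent, plus the center point. Rays lie in the x-y plane, spread
#' evenly within +/-60 degrees of the in-plane path normal (on both sides):
#' the axial elongation of the two-photon point-spread function makes the
#' z profile of even a perfect tube much wider than its x-y profile, so rays
#' leaving the x-y plane would dominate the fit residual with a constant
#' anisotropy term and drown out the tube/body contrast the base detection
#' relies on. An ideal
#' isotropic Gaussian \eqn{A e^{-r^2/2\sigma^2} + b} is fitted to
#' the radially averaged profile: `b` is the image's dark background level
#' (median intensity of the frame — tying the offset to the true background
#' is what makes a broad, non-decaying profile inside the terminal body score
#' badly), `A` is the center sample above background, and \eqn{\sigma} comes
#' from the half-maximum radius of the profile (capped, so that a profile
#' that never decays is fitted by a Gaussian that must — and misfits).
#' The returned RMSD between fit and all samples is low inside a thin tube
#' and high inside the broad terminal body, and — since `b` shifts with any
#' global offset, `A` and the RMSD scale with any global gain — the
#' downstream change-point detection (relative threshold) is invariant to
#' affine intensity rescaling. Sampling is done in world micrometers, so the
#' anisotropic z axis is handled correctly.
#'
#' @param image a [grid_image()].
#' @param point world position (um) on the path.
#' @param tangent local path direction (world um, need not be unit length).
#' @param params a [filo_params()] (uses `k_rays`, `n_radii`, `r_max`).
#' @param background dark background level; `NULL` computes the frame median
#'   (callers evaluating many path points should compute it once).
#' @return non-negative RMSD (intensity units).
#' @export
gaussianness <- function(image, point, tangent, params = filo_params(),
                         background = NULL) {
  if (is.null(background)) background <- stats::median(image$values)
  if (sum(tangent^2) == 0) stop("zero tangent")
  d <- dim(image$values)
  # shrink r_max if the sampling disc would leave the volume
  lo <- point - image$origin
  hi <- image$origin + (d - 1) * image$spacing - point
  room <- max(min(lo, hi), image$spacing[1])
  r_max <- min(params$r_max, room)

  # in-plane normal to the path; fall back to x for near-vertical tangents
  txy <- tangent[1:2]
  nrm <- if (sum(txy^2) > 1e-12) c(-txy[2], txy[1]) / sqrt(sum(txy^2))
         else c(1, 0)
  base_ang <- atan2(nrm[2], nrm[1])
  half <- max(1L, params$k_rays %/% 2L)
  spread <- if (half > 1) seq(-pi / 4, pi / 4, length.out = half) else 0
  angles <- c(base_ang + spread, base_ang + pi + spread)
  cosfac <- abs(cos(c(spread, spread)))   # obliqueness wrt the tube normal
  radii <- r_max * seq_len(params$n_radii) / params$n_radii
  dirs <- cbind(cos(angles), sin(angles), 0)
  offs <- do.call(rbind, lapply(radii, function(r) r * dirs))

  # traced paths run on voxel centers, up to half a voxel off the true
  # ridge; a shifted Gaussian misfits a centered model badly, so recenter
  # onto the local intensity centroid along the in-plane normal first
  samp <- interp_trilinear(image, sweep(offs, 2, point, "+"))
  w0 <- pmax(samp - background, 0)
  s_along <- offs[, 1] * nrm[1] + offs[, 2] * nrm[2]
  if (sum(w0) > 1e-9) {
    delta <- sum(w0 * s_along) / sum(w0)
    delta <- max(min(delta, image$spacing[1]), -image$spacing[1])
    point <- point + delta * c(nrm, 0)
  }

  pts <- sweep(offs, 2, point, "+")
  samp <- interp_trilinear(image, pts)
  c0 <- interp_trilinear(image, matrix(point, ncol = 3))
  # an oblique ray crosses the tube at perpendicular distance r*cos(chi);
  # fitting against that effective radius makes a straight Gaussian tube an
  # exact model regardless of ray angle
  r_eff <- rep(radii, each = length(angles)) * rep(cosfac, times = length(radii))

  bg <- background
  A <- c0 - bg
  # sigma from the half-maximum radius of the radially averaged profile:
  # robust to truncation of a wide profile at r_max, where a second-moment
  # estimate is biased low. The cap at 0.6 r_max is essential: a flat body
  # profile has no half-max crossing, and capping sigma forces the fitted
  # Gaussian to decay, so the body misfits and the change point is visible.
  rs <- sort(unique(round(r_eff, 9)))
  Pm <- vapply(rs, function(r) mean(samp[abs(r_eff - r) < 1e-8]), numeric(1))
  rr <- c(0, rs); PP <- c(c0, Pm)
  sig_cap <- 0.6 * r_max
  r_half <- NA_real_
  if (A > 1e-6) {
    lvl <- bg + A / 2
    for (j in seq_len(length(rr) - 1)) {
      if (PP[j] >= lvl && PP[j + 1] < lvl) {
        fr <- (PP[j] - lvl) / (PP[j] - PP[j + 1])
        r_half <- rr[j] + fr * (rr[j + 1] - rr[j])
        break
      }
    }
  }
  sigma <- if (is.na(r_half)) sig_cap
           else max(min(r_half / 1.17741, sig_cap), image$spacing[1] / 2)
  sigma2 <- sigma^2
  model <- function(r) A * exp(-r^2 / (2 * sigma2)) + bg
  resid2 <- (c(c0, samp) - model(c(0, r_eff)))^2
  # trimmed RMSD: a stray ray grazing a neighboring filopodium must not
  # masquerade as the terminal body
  drop <- floor(params$trim * length(resid2))
  if (drop > 0) resid2 <- sort(resid2)[seq_len(length(resid2) - drop)]
  sqrt(mean(resid2))
}

#' Locate the filopodium base along a traced path
#'
#' Computes the smoothed (3-point moving average) Gaussian-ness RMSD at every
#' path point and thresholds it at \eqn{\tau = \kappa \cdot} the median RMSD
#' over the distal (tip-side) quarter of the path. The terminal body extends
#' from the base to the root, so its suprathreshold region always reaches the
#' root end of the path; RMSD peaks caused by crossing branches or the
#' limited axial resolution are interior and never do. The base is therefore
#' placed at the onset of the \emph{final} suprathreshold run (sub-`run_um`
#' dips are bridged), refined to the plateau-onset point of the rise, since
#' the base lies on the body surface where the profile is already body-like.
#'
#' @param image a [grid_image()].
#' @param polyline n x 3 matrix (world um), ordered tip to root.
#' @param params a [filo_params()].
#' @return list with `index` (row of `polyline`), `point` (world um),
#'   `flagged` (TRUE when no change point was found or the path was too short,
#'   in which case the base defaults to the root-adjacent point and should be
#'   proofread), and `rmsd` (the smoothed profile per point, for inspection).
#' @export
estimate_base <- function(image, polyline, params = filo_params()) {
  polyline <- dedupe_polyline(polyline)
  n <- nrow(polyline)
  if (n < 8) {
    return(list(index = max(n - 1L, 1L),
                point = polyline[max(n - 1L, 1L), ],
                flagged = TRUE, rmsd = rep(NA_real_, n)))
  }
  # central-difference tangents over +/- 2 points
  idx_lo <- pmax(seq_len(n) - 2L, 1L)
  idx_hi <- pmin(seq_len(n) + 2L, n)
  bg <- stats::median(image$values)
  raw <- vapply(seq_len(n), function(i) {
    tg <- polyline[idx_hi[i], ] - polyline[idx_lo[i], ]
    if (sum(tg^2) == 0) return(NA_real_)
    gaussianness(image, polyline[i, ], tg, params, background = bg)
  }, numeric(1))
  raw[is.na(raw)] <- stats::median(raw, na.rm = TRUE)
  sm <- stats::filter(raw, rep(1 / 3, 3), sides = 2)
  sm[1] <- raw[1]; sm[n] <- raw[n]
  sm <- as.numeric(sm)

  distal <- seq_len(max(2L, ceiling(n / 4)))
  tau <- params$kappa * stats::median(sm[distal])
  if (tau <= 0) tau <- .Machine$double.eps

  steps <- c(0, cumsum(sqrt(rowSums(diff(polyline)^2))))
  first_distal <- distal[length(distal)] + 1L

  # The terminal body extends from the base all the way to the root, so its
  # suprathreshold RMSD region always reaches the root end of the path.
  # Interior peaks — branch crossings — never do, however wide they are.
  # The base therefore bounds the FINAL suprathreshold run; dips shorter
  # than run_um (noise) are merged into it.
  above <- which(sm > tau)
  above <- above[above > first_distal]
  if (!length(above))
    return(list(index = n - 1L, point = polyline[n - 1L, ], flagged = TRUE,
                rmsd = sm))
  i <- max(above)
  j <- i - 1L
  while (j > first_distal) {
    if (sm[j] > tau) { i <- j; j <- j - 1L; next }
    k <- j
    while (k > first_distal && sm[k] <= tau) k <- k - 1L
    if (sm[k] <= tau || steps[j] - steps[k] >= params$run_um) break
    i <- k; j <- k - 1L
  }
  # refine along the rise between tube floor and body plateau: the base sits
  # on the body surface, where the profile is already body-like, so take the
  # plateau-onset (80% rise) point rather than the raw tau crossing
  floor_v <- stats::median(sm[distal])
  plateau <- stats::median(sm[i:n])
  thr2 <- floor_v + 0.8 * (plateau - floor_v)
  k <- i
  if (sm[k] >= thr2) {
    while (k > first_distal && sm[k - 1L] >= thr2) k <- k - 1L
  } else {
    while (k < n && sm[k] < thr2) k <- k + 1L
  }
  list(index = k, point = polyline[k, ], flagged = FALSE, rmsd = sm)
}
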