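#' 3D intensity volume with anisotropic voxel spacing
#'
#' A `grid_image` stores one time step of a single-channel microscopy volume:
#' an `[x, y, z]` array of intensities in `[0, 255]`, the physical voxel
#' spacing in micrometers per axis, and the world position of the center of
#' voxel `(1, 1, 1)`. Two-photon stacks are strongly anisotropic (typically
#' 0.1 x 0.1 x 0.5 um), so all geometry downstream is done in world
#' micrometers, never in voxel index units.
#'
#' Voxel indices are 1-based; world coordinates refer to voxel centers.
#'
#' @param values numeric 3D array `[x, y, z]`, intensities in `[0, 255]`.
#' @param spacing numeric length-3, micrometers per voxel along x, y, z.
#' @param origin numeric length-3, world position (um) of voxel (1,1,1).
#' @param time_index non-negative integer time step.
#' @return object of class `grid_image`.
#' @export
grid_image <- function(values, spacing, origin = c(0, 0, 0), time_index = 0L) {
  stopifnot(length(dim(values)) == 3, length(spacing) == 3,
            length(origin) == 3, all(spacing > 0))
  rng <- range(values)
  if (rng[1] < 0 || rng[2] > 255)
    stop("intensities must lie in [0, 255]; got [",
         rng[1], ", ", rng[2], "]")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 time_index = as.integer(time_index)),
            class = "grid_image")
}

#' @export
print.grid_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("grid_image %d x %d x %d voxels, spacing (%g, %g, %g) um, t = %d\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$time_index))
  invisible(x)
}

#' @export
dim.grid_image <- function(x) dim(x$values)

#' Convert between world (um) and voxel coordinates
#'
#' `world_to_voxel` returns the 1-based index of the voxel whose center is
#' nearest to `p` (i.e. the voxel containing `p`); `voxel_to_world` returns
#' the world position of a voxel center. The two are mutually inverse up to
#' voxel quantization: `voxel_to_world(world_to_voxel(p))` is the center of
#' the voxel containing `p`.
#'
#' @param image a [grid_image()].
#' @param p world coordinates (um), length 3 or an n x 3 matrix.
#' @param v voxel indices (1-based), length 3 or an n x 3 matrix.
#' @return integer voxel indices / numeric world coordinates, same shape as
#'   the input.
#' @export
world_to_voxel <- function(image, p) {
  was_vec <- !is.matrix(p)
  p <- to_mat3(p)
  v <- sweep(sweep(p, 2, image$origin, "-"), 2, image$spacing, "/")
  v <- round(v) + 1
  d <- dim(image$values)
  if (any(v < 1) || any(sweep(v, 2, d, ">")))
    stop("world point outside image bounds")
  out <- matrix(as.integer(v), ncol = 3)
  if (was_vec) drop(out) else out
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(image, v) {
  was_vec <- !is.matrix(v)
  v <- to_mat3(v)
  d <- dim(image$values)
  if (any(v < 1) || any(sweep(v, 2, d, ">")))
    stop("voxel index outside lattice")
  w <- sweep(sweep(v - 1, 2, image$spacing, "*"), 2, image$origin, "+")
  if (was_vec) drop(w) else w
}

to_mat3 <- function(p) {
  if (is.matrix(p)) { stopifnot(ncol(p) == 3); p } else {
    stopifnot(length(p) == 3); matrix(p, ncol = 3)
  }
}

#' Inclusive axis-aligned voxel box
#'
#' @param lo,hi 1-based inclusive voxel bounds per axis, `lo <= hi`.
#' @return object of class `box3d` with fields `lo`, `hi`.
#' @export
box3d <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  stopifnot(length(lo) == 3, length(hi) == 3, all(lo <= hi))
  structure(list(lo = lo, hi = hi), class = "box3d")
}

box_size <- function(box) box$hi - box$lo + 1L

clip_box <- function(box, dims) {
  box3d(pmax(box$lo, 1L), pmin(box$hi, as.integer(dims)))
}

#' Crop a volume to a voxel box
#'
#' The origin of the result is shifted so that the world coordinates of the
#' retained voxels are unchanged: cropping never moves geometry.
#'
#' @param image a [grid_image()].
#' @param box a [box3d()] inside the lattice.
#' @return cropped [grid_image()].
#' @export
crop <- function(image, box) {
  d <- dim(image$values)
  if (any(box$lo < 1) || any(box$hi > d))
    stop("crop box exceeds lattice bounds")
  vals <- image$values[box$lo[1]:box$hi[1],
                       box$lo[2]:box$hi[2],
                       box$lo[3]:box$hi[3], drop = FALSE]
  grid_image(vals, image$spacing,
             image$origin + (box$lo - 1) * image$spacing,
             image$time_index)
}

#' Time-lapse series of volumes
#'
#' All frames share lattice dimensions and spacing; origins may differ, since
#' cropped frames follow the (drifting) axon terminal. `dt` is the time
#' between consecutive frames in minutes.
#'
#' @param frames list of [grid_image()], time indices strictly increasing.
#' @param dt frame interval (minutes).
#' @return object of class `time_series`.
#' @export
time_series <- function(frames, dt = 1) {
  stopifnot(length(frames) >= 1, dt > 0)
  d0 <- dim(frames[[1]]$values); s0 <- frames[[1]]$spacing
  for (f in frames) {
    stopifnot(inherits(f, "grid_image"))
    if (!identical(dim(f$values), d0))
      stop("all frames must share lattice dimensions")
    if (!isTRUE(all.equal(f$spacing, s0)))
      stop("all frames must share voxel spacing")
  }
  ti <- vapply(frames, function(f) f$time_index, integer(1))
  if (any(diff(ti) <= 0)) stop("time indices must be strictly increasing")
  structure(list(frames = frames, dt = dt), class = "time_series")
}

#' @export
length.time_series <- function(x) length(x$frames)

#' @export
print.time_series <- function(x, ...) {
  d <- dim(x$frames[[1]]$values)
  cat(sprintf("time_series: %d frames of %d x %d x %d voxels, dt = %g min\n",
              length(x$frames), d[1], d[2], d[3], x$dt))
  invisible(x)
}

# tiff::readTIFF returns matrices [row, col] = [y, x]; transpose to [x, y].
pages_to_array <- function(pages) {
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(pg) {
    if (length(dim(pg)) == 3) pg <- pg[, , 1]  # first channel only
    t(pg)
  })
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr
}

rescale_to_8bit <- function(arr) {
  rng <- range(arr)
  if (rng[1] >= 0 && rng[2] <= 1.000001 && rng[2] > 0) {
    # tiff package scales integer data to [0,1] unless as.is succeeds
    round(arr * 255)
  } else if (rng[2] > 255) {
    # >8-bit input: min-max rescale to [0,255]
    if (rng[2] > rng[1]) round((arr - rng[1]) / (rng[2] - rng[1]) * 255)
    else arr * 0
  } else arr
}

#' Load a time-lapse TIFF series
#'
#' Accepts either a multi-page TIFF holding all frames (pages are z-slices,
#' frames concatenated; `nz` gives slices per frame) or a directory of
#' per-frame TIFFs. Directory entries carrying a time index in their name
#' (`t<number>`, e.g. `frame_t003.tif`) are ordered by that index, otherwise
#' lexically. Intensities beyond 8 bit are min-max rescaled to `[0, 255]` and
#' rounded.
#'
#' @param path TIFF file or directory of TIFFs.
#' @param spacing voxel spacing (um), length 3; always supplied by the user,
#'   never read from file metadata.
#' @param dt frame interval (minutes).
#' @param nz z-slices per frame; required for a single multi-page file holding
#'   more than one frame.
#' @return a [time_series()].
#' @export
load_series <- function(path, spacing, dt = 1, nz = NULL) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0) stop("no TIFF files in directory: ", path)
    tidx <- suppressWarnings(
      as.integer(sub(".*[tT](\\d+)\\D*\\.[tT][iI][fF][fF]?$", "\\1",
                     basename(files))))
    ord <- if (all(!is.na(tidx)) && !anyDuplicated(tidx)) order(tidx)
           else order(basename(files))
    files <- files[ord]
    frames <- lapply(seq_along(files), function(k) {
      arr <- rescale_to_8bit(pages_to_array(
        tiff::readTIFF(files[k], all = TRUE, as.is = TRUE)))
      grid_image(arr, spacing, time_index = k - 1L)
    })
  } else {
    arr <- rescale_to_8bit(pages_to_array(
      tiff::readTIFF(path, all = TRUE, as.is = TRUE)))
    npages <- dim(arr)[3]
    if (is.null(nz)) nz <- npages
    if (npages %% nz != 0)
      stop("page count ", npages, " not divisible by nz = ", nz)
    frames <- lapply(seq_len(npages / nz), function(k) {
      grid_image(arr[, , ((k - 1) * nz + 1):(k * nz), drop = FALSE],
                 spacing, time_index = k - 1L)
    })
  }
  time_series(frames, dt)
}

#' Write one volume as an 8-bit multi-page TIFF
#'
#' Pages are z-slices; intensities are stored as 8-bit so a write/read
#' round-trip is bit-exact for integer-valued images.
#'
#' @param image a [grid_image()].
#' @param path output file.
#' @export
write_frame <- function(image, path) {
  pages <- lapply(seq_len(dim(image$values)[3]),
                  function(k) t(image$values[, , k]) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a series as one TIFF per frame
#'
#' Files are named `frame_t<index>.tif` so [load_series()] restores the
#' original order.
#'
#' @param series a [time_series()].
#' @param dir output directory (created if missing).
#' @return character vector of written paths.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(series$frames, function(f) {
    p <- file.path(dir, sprintf("frame_t%03d.tif", f$time_index))
    write_frame(f, p)
    p
  }, character(1))
}
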