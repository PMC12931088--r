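#' Workflow parameter set
#'
#' Bundles every user-adjustable parameter of the reconstruction workflow with
#' its default. Defaults are the values used on the two-photon R7 axon
#' terminal data the workflow was developed on; all of them can be overridden
#' per call or via a YAML/JSON config file (see [read_config()]).
#'
#' @param theta intensity threshold (0-255) used by crop-box estimation to
#'   separate foreground from background.
#' @param persistence intensity prominence (0-255): a foreground component
#'   whose peak rises less than this above `theta` is merged into its
#'   brightest neighbor during crop-box estimation.
#' @param c intensity weight (>= 0) of the tracing edge weight; balances the
#'   Euclidean step length against the dark-voxel penalty.
#' @param i_max brightness cap (0-255) for the tracing weight; intensities at
#'   or above it are equally "bright enough", so long detours through very
#'   bright voxels are not rewarded.
#' @param n_margin margin, in voxels per dimension, by which the bounding box
#'   of two endpoints is dilated before an on-the-fly pairwise trace.
#' @param d maximum distance in micrometers that two nodes may be apart and
#'   still be considered the same filopodium when linking across time steps.
#' @param l_min minimum base-to-tip length in micrometers; shorter propagated
#'   filopodia are considered retracted and removed.
#' @param root_template,root_search integer voxel sizes (length-3) of the NCC
#'   template and search window used to propagate the terminal center.
#' @param root_gamma NCC acceptance threshold in `[0,1]` for the root.
#' @param base_template,base_search,base_gamma same, for filopodium bases.
#' @param tip_template,tip_search,tip_gamma same, for filopodium tips.
#' @param k_rays number of rays of the radial sampling pattern used by base
#'   detection.
#' @param n_radii number of radii per ray.
#' @param r_max outermost sampling radius in micrometers; spans a
#'   filopodium's transverse profile (about 2.5-3 sigma) while staying clear
#'   of the axon body and of neighboring filopodia in a crowded terminal.
#' @param trim fraction of the largest profile-fit residuals discarded when
#'   computing the RMSD; makes the score robust to a single ray grazing a
#'   neighboring structure.
#' @param branch_margin junction-to-base path distance (um) below which a
#'   path joining an existing filopodium is classified as an independent
#'   filopodium sharing the base site instead of a branch (see
#'   [insert_path()]).
#' @param kappa change-point factor: the base is placed where the smoothed
#'   profile-fit RMSD exceeds `kappa` times the median RMSD over the distal
#'   quarter of the path.
#' @param run_um path length in micrometers over which the RMSD exceedance
#'   must be sustained, so that short branch-induced RMSD peaks do not trigger
#'   the base.
#'
#' @return An object of class `filo_params` (a named list).
#' @export
filo_params <- function(theta = 50, persistence = 150,
                        c = 50, i_max = 100, n_margin = 10,
                        d = 1.0, l_min = 0.5,
                        root_template = c(15L, 15L, 3L),
                        root_search = c(70L, 70L, 7L),
                        root_gamma = 0.8,
                        base_template = c(10L, 10L, 4L),
                        base_search = c(50L, 50L, 10L),
                        base_gamma = 0.8,
                        tip_template = c(10L, 10L, 4L),
                        tip_search = c(15L, 15L, 4L),
                        tip_gamma = 0.8,
                        k_rays = 8L, n_radii = 5L, r_max = 0.35,
                        trim = 0.1, branch_margin = 0.3,
                        kappa = 3, run_um = 0.5) {
  p <- list(theta = theta, persistence = persistence,
            c = c, i_max = i_max, n_margin = as.integer(n_margin),
            d = d, l_min = l_min,
            root_template = as.integer(root_template),
            root_search = as.integer(root_search),
            root_gamma = root_gamma,
            base_template = as.integer(base_template),
            base_search = as.integer(base_search),
            base_gamma = base_gamma,
            tip_template = as.integer(tip_template),
            tip_search = as.integer(tip_search),
            tip_gamma = tip_gamma,
            k_rays = as.integer(k_rays), n_radii = as.integer(n_radii),
            r_max = r_max, trim = trim, branch_margin = branch_margin,
            kappa = kappa, run_um = run_um)
  stopifnot(p$c >= 0, p$i_max >= 1, p$i_max <= 255,
            p$n_margin >= 0, p$d > 0, p$l_min >= 0,
            p$root_gamma >= 0, p$root_gamma <= 1,
            p$base_gamma >= 0, p$base_gamma <= 1,
            p$tip_gamma >= 0, p$tip_gamma <= 1,
            all(p$root_template > 0), all(p$root_search > 0),
            all(p$base_template > 0), all(p$base_search > 0),
            all(p$tip_template > 0), all(p$tip_search > 0),
            p$k_rays >= 3, p$n_radii >= 2, p$r_max > 0, p$kappa > 0,
            p$trim >= 0, p$trim < 0.5)
  class(p) <- "filo_params"
  p
}

#' Read workflow configuration from YAML or JSON
#'
#' The file may contain any subset of [filo_params()] arguments plus the
#' acquisition fields `spacing` (length-3, micrometers per voxel) and `dt`
#' (minutes between frames).
#'
#' @param path config file (`.yaml`/`.yml`/`.json`).
#' @return list with elements `params` (`filo_params`), `spacing`, `dt`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  spacing <- if (!is.null(cfg$spacing)) as.numeric(cfg$spacing) else c(0.1, 0.1, 0.5)
  dt <- if (!is.null(cfg$dt)) as.numeric(cfg$dt) else 1
  keep <- intersect(names(cfg), names(formals(filo_params)))
  params <- do.call(filo_params, cfg[keep])
  list(params = params, spacing = spacing, dt = dt)
}

#' @export
print.filo_params <- function(x, ...) {
  cat("filopodia workflow parameters\n")
  for (nm in names(x)) cat(sprintf("  %-14s %s\n", nm, paste(x[[nm]], collapse = " ")))
  invisible(x)
}
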