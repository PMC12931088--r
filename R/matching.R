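# Normalized cross-correlation template matching, used to propagate root,
# base and tip nodes between consecutive time steps. NCC is invariant to
# per-frame gain/offset intensity changes, which two-photon time series
# routinely show.

#' Normalized cross correlation of two equal-shaped patches
#'
#' \deqn{\mathrm{NCC}(a,b) = \frac{\sum (a-\bar a)(b-\bar b)}
#'   {\|a-\bar a\| \, \|b-\bar b\|} \in [-1, 1]}
#' A patch with zero variance makes the score undefined; 0 is returned with
#' attribute `unmatchable = TRUE` so callers can fall back to the previous
#' node position.
#'
#' @param a,b numeric arrays/vectors of identical length.
#' @return score in `[-1, 1]`.
#' @export
ncc <- function(a, b) {
  if (length(a) != length(b)) stop("patches must have identical shape")
  s <- ncc_cpp(as.numeric(a), as.numeric(b))
  if (is.na(s)) return(structure(0, unmatchable = TRUE))
  s
}

#' Propagate a node position by exhaustive NCC template matching
#'
#' The image region of size `template` around `center_prev` in the previous
#' frame is the template. It is repositioned to every voxel center inside the
#' search window of size `search` (centered at `center_prev`'s voxel position
#' in the current frame) and the NCC is computed at each offset; the offset
#' with the maximal score wins. Boxes are clipped at image borders and the
#' score is computed on the clipped overlap, since tips often sit near crop
#' boundaries. The match is accepted iff the best score reaches `gamma`;
#' otherwise the caller keeps the previous position. For even box sizes the
#' center voxel is the floor-half index. Score ties are broken by the smaller
#' displacement, then lexicographically, so results are deterministic.
#'
#' @param img_prev,img_cur [grid_image()] frames at `t` and `t+1` (same
#'   lattice dimensions).
#' @param center_prev 1-based voxel index (length 3) in `img_prev`.
#' @param template,search integer voxel box sizes (length 3).
#' @param gamma NCC acceptance threshold in `[0, 1]`.
#' @return list with `best_position` (voxel index), `best_ncc`, `accepted`,
#'   `found` (FALSE when every candidate was flat or out of bounds).
#' @export
match_template <- function(img_prev, img_cur, center_prev,
                           template, search, gamma = 0.8) {
  dp <- dim(img_prev$values); dc <- dim(img_cur$values)
  center_prev <- as.integer(center_prev)
  if (any(center_prev < 1) || any(center_prev > dp))
    stop("center outside previous frame")
  res <- match_template_cpp(as.numeric(img_prev$values), as.integer(dp),
                            as.numeric(img_cur$values), as.integer(dc),
                            center_prev, as.integer(template),
                            as.integer(search))
  score <- res$best_ncc
  list(best_position = as.integer(res$best_pos),
       best_ncc = score,
       accepted = isTRUE(res$found) && score >= gamma,
       found = isTRUE(res$found))
}
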