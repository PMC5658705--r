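# Single-molecule spot detection with the fast radial symmetry transform
# (gradient-orientation voting; bright polarity only, since fluorescent
# spots are bright on a dark background), plus assignment of detected
# spots to segmented cells through the inter-camera transform.

# Separable Gaussian blur with replicate edge padding.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], half), v, rep(v[n], half))
    as.numeric(stats::filter(vp, k, sides = 2))[(half + 1):(half + n)]
  }
  x <- apply(x, 2, conv1)
  t(apply(x, 1, conv1))
}

#' Fast radial symmetry transform
#'
#' For each radius n, every pixel with sufficient gradient magnitude votes
#' at the point n pixels up its intensity gradient (towards a bright
#' center), building an orientation-count image O_n and a magnitude image
#' M_n. These are normalized, raised to the radial-strictness power
#' `alpha`, smoothed, and averaged over radii. Radially symmetric bright
#' blobs of matching radius produce strong maxima.
#'
#' @param frame numeric matrix.
#' @param radii integer radii in pixels (defaults suit a spot sigma of
#'   about 1.3 px).
#' @param alpha radial strictness; larger suppresses elongated structures.
#' @param grad_threshold_frac ignore gradients below this fraction of the
#'   maximum gradient magnitude.
#' @return Response matrix of the same size as `frame`.
#' @export
radial_symmetry_transform <- function(frame, radii = c(2, 3), alpha = 2,
                                      grad_threshold_frac = 0.05) {
  stopifnot(all(radii >= 1), alpha > 0)
  nr <- nrow(frame); nc <- ncol(frame)
  gr <- matrix(0, nr, nc); gc <- matrix(0, nr, nc)
  gr[2:(nr - 1), ] <- (frame[3:nr, ] - frame[1:(nr - 2), ]) / 2
  gc[, 2:(nc - 1)] <- (frame[, 3:nc] - frame[, 1:(nc - 2)]) / 2
  gmax <- max(sqrt(gr^2 + gc^2))
  if (gmax == 0) return(matrix(0, nr, nc))
  S <- matrix(0, nr, nc)
  for (n in radii) {
    vote <- cpp_frst_vote(gr, gc, as.integer(n),
                          grad_threshold_frac * gmax)
    kn <- if (n == 1) 8 else 9.9
    O <- pmin(vote$O, kn)
    FF <- (O / kn)^alpha * (vote$M / kn)
    S <- S + gaussian_blur(matrix(FF, nr, nc), 0.5 * n)
  }
  S / length(radii)
}

#' Detect spots in a radial-symmetry response
#'
#' Local maxima above a robust threshold, with non-maximum suppression at
#' `min_separation_px` and sub-pixel refinement by a quadratic fit to the
#' 3x3 neighborhood. The threshold is `k` MADs above the median of the
#' local-maxima response population (not of all pixels): the radial
#' symmetry response is strongly kurtotic, so the pixel-wise MAD reflects
#' flat background rather than the noise peaks that false positives come
#' from.
#'
#' @param response raster from [radial_symmetry_transform].
#' @param k threshold in MADs above the median of the candidate (local
#'   maxima) responses.
#' @param min_separation_px minimum distance between detections; of two
#'   closer maxima only the stronger is kept.
#' @param frame_index stored in the output.
#' @return `data.frame(frame, row, col, response)` with 0-based sub-pixel
#'   (row, col) positions, strongest first.
#' @export
detect_spots <- function(response, k = 8, min_separation_px = 3,
                         frame_index = 0L) {
  nr <- nrow(response); nc <- ncol(response)
  maxima <- cpp_local_maxima(response, 1L) & response > 0
  out <- data.frame(frame = integer(), row = numeric(), col = numeric(),
                    response = numeric())
  if (!any(maxima)) return(out)
  # noise peaks are roughly log-normal while true spots sit orders of
  # magnitude higher, so the robust threshold is taken in log domain
  pk <- log(response[maxima])
  thr <- exp(median(pk) + k * mad(pk))
  idx <- which(maxima & response > thr)
  if (length(idx) == 0) return(out)
  r <- (idx - 1) %% nr + 1
  c <- (idx - 1) %/% nr + 1
  ord <- order(response[idx], decreasing = TRUE)
  r <- r[ord]; c <- c[ord]; v <- response[idx][ord]
  keep <- logical(length(r))
  for (i in seq_along(r)) {
    sel <- which(keep)
    if (length(sel) && any((r[sel] - r[i])^2 + (c[sel] - c[i])^2 <
                           min_separation_px^2)) next
    keep[i] <- TRUE
  }
  r <- r[keep]; c <- c[keep]; v <- v[keep]
  refine <- function(ri, ci) {
    dr <- dc <- 0
    if (ri > 1 && ri < nr) {
      num <- response[ri - 1, ci] - response[ri + 1, ci]
      den <- response[ri - 1, ci] - 2 * response[ri, ci] +
        response[ri + 1, ci]
      if (den != 0) dr <- max(min(0.5 * num / den, 0.5), -0.5)
    }
    if (ci > 1 && ci < nc) {
      num <- response[ri, ci - 1] - response[ri, ci + 1]
      den <- response[ri, ci - 1] - 2 * response[ri, ci] +
        response[ri, ci + 1]
      if (den != 0) dc <- max(min(0.5 * num / den, 0.5), -0.5)
    }
    c(dr, dc)
  }
  off <- t(mapply(refine, r, c))
  data.frame(frame = frame_index,
             row = r - 1 + off[, 1], col = c - 1 + off[, 2],
             response = v)
}

#' Assign detected spots to segmented cells
#'
#' Maps each spot position from fluorescence-camera to phase-camera
#' coordinates through the inter-camera transform, then assigns it to the
#' label of the nearest-in-time segmentation mask at the mapped pixel.
#' Spots landing on background are rescued to the closest cell within
#' `rescue_radius_px`, else left unassigned (label 0).
#'
#' @param spots `data.frame` from [detect_spots] (0-based row/col in
#'   fluorescence-camera coordinates).
#' @param transform [affine_transform] from fluorescence to phase
#'   coordinates.
#' @param mask [label_mask] of the nearest-in-time phase frame.
#' @param rescue_radius_px background-rescue search radius.
#' @return `list(spots =, counts =)`: the input with `cell` (assigned
#'   label, 0 = unassigned) and mapped coordinates appended, and a
#'   per-cell count table (cell, n_spots) over all mask labels.
#' @export
assign_spots_to_cells <- function(spots, transform, mask,
                                  rescue_radius_px = 2) {
  nr <- nrow(mask); nc <- ncol(mask)
  labs <- setdiff(sort(unique(as.vector(mask))), 0L)
  cell <- integer(nrow(spots))
  mapped <- if (nrow(spots) > 0)
    apply_transform(transform, cbind(spots$row, spots$col)) else
      matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(spots))) {
    ri <- round(mapped[i, 1]) + 1; ci <- round(mapped[i, 2]) + 1
    lab <- if (ri >= 1 && ri <= nr && ci >= 1 && ci <= nc)
      mask[ri, ci] else 0L
    rad <- ceiling(rescue_radius_px)
    if (lab == 0L && rescue_radius_px > 0 &&
        ri + rad >= 1 && ri - rad <= nr && ci + rad >= 1 && ci - rad <= nc) {
      rr <- max(1, ri - rad):min(nr, ri + rad)
      cc <- max(1, ci - rad):min(nc, ci + rad)
      if (TRUE) {
        win <- mask[rr, cc, drop = FALSE]
        cand <- which(win > 0)
        if (length(cand) > 0) {
          d2 <- (rr[(cand - 1) %% length(rr) + 1] - mapped[i, 1] - 1)^2 +
            (cc[(cand - 1) %/% length(rr) + 1] - mapped[i, 2] - 1)^2
          j <- which.min(d2)
          if (d2[j] <= rescue_radius_px^2) lab <- win[cand[j]]
        }
      }
    }
    cell[i] <- lab
  }
  spots$cell <- cell
  spots$row_phase <- if (nrow(spots)) mapped[, 1] else numeric(0)
  spots$col_phase <- if (nrow(spots)) mapped[, 2] else numeric(0)
  counts <- data.frame(cell = labs,
                       n_spots = vapply(labs, function(l) sum(cell == l),
                                        integer(1)))
  list(spots = spots, counts = counts)
}
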