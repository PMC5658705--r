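# Phase-contrast preprocessing and cell segmentation. Cells appear dark on
# a light background; an empty reference trap is subtracted (after a small
# integer-pixel alignment search) to remove the static channel structure,
# then cells are found by Otsu thresholding of the corrected image and
# touching cells are split by a distance-transform watershed.

#' Otsu's threshold
#'
#' Maximizes between-class variance over a fixed-bin histogram.
#'
#' @param x numeric vector or matrix of intensities.
#' @param n_bins number of histogram bins.
#' @return The threshold intensity.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(
    findInterval(v, seq(rng[1], rng[2], length.out = n_bins + 1L),
                 rightmost.closed = TRUE), 1L), n_bins), n_bins)
  p <- h / sum(h)
  mids <- seq(rng[1], rng[2], length.out = n_bins + 1L)[-1] -
    diff(rng) / (2 * n_bins)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Subtract an empty reference trap from a phase-contrast frame
#'
#' Removes the static trap structure by deducting the image of a trap
#' designed to hold no cells. The reference is first registered to the
#' frame by an exhaustive integer-pixel translation search (minimum mean
#' squared difference over the overlap); the output is signed.
#'
#' @param frame phase-contrast raster (matrix).
#' @param empty_ref empty-trap reference raster, same dimensions.
#' @param max_shift_px translation search window (+/- pixels in each axis).
#' @return Corrected signed raster with attribute `shift` (row, col) of the
#'   reference alignment.
#' @export
subtract_empty_trap <- function(frame, empty_ref, max_shift_px = 3L) {
  if (!all(dim(frame) == dim(empty_ref)))
    stop("frame and empty reference must share dimensions")
  nr <- nrow(frame); nc <- ncol(frame)
  best <- c(0L, 0L); best_mse <- Inf
  for (dr in -max_shift_px:max_shift_px) {
    for (dc in -max_shift_px:max_shift_px) {
      # overlap of frame[r, c] with empty_ref[r - dr, c - dc]
      r_f <- max(1, 1 + dr):min(nr, nr + dr)
      c_f <- max(1, 1 + dc):min(nc, nc + dc)
      mse <- mean((frame[r_f, c_f] -
                     empty_ref[r_f - dr, c_f - dc])^2)
      if (mse < best_mse) { best_mse <- mse; best <- c(dr, dc) }
    }
  }
  shifted <- matrix(median(empty_ref), nr, nc)
  r_f <- max(1, 1 + best[1]):min(nr, nr + best[1])
  c_f <- max(1, 1 + best[2]):min(nc, nc + best[2])
  shifted[r_f, c_f] <- empty_ref[r_f - best[1], c_f - best[2]]
  out <- frame - shifted
  attr(out, "shift") <- best
  out
}

#' Segment cells in a corrected phase-contrast frame
#'
#' Thresholds the background-subtracted image (cells are dark, so the
#' negated corrected image is bright where cells are), labels 4-connected
#' components, splits touching cells with a watershed on the negated
#' Euclidean distance transform seeded at distance maxima, removes
#' components outside the area bounds, and renumbers labels 1..K from the
#' top of the trap down.
#'
#' @param corrected signed raster from [subtract_empty_trap].
#' @param min_area_px,max_area_px component area bounds (pixels).
#' @param polarity `"dark"` (default) when cells are darker than
#'   background, `"bright"` otherwise.
#' @param split_touching if `TRUE` (default) apply the watershed split.
#' @param seed_fraction watershed seeds are the connected regions where the
#'   distance transform reaches at least this fraction of its maximum;
#'   touching rods have a distance dip at their junction, so each cell body
#'   yields one seed blob.
#' @return A [label_mask].
#' @export
segment_cells <- function(corrected, min_area_px = 20, max_area_px = 1000,
                          polarity = c("dark", "bright"),
                          split_touching = TRUE,
                          seed_fraction = 0.6) {
  polarity <- match.arg(polarity)
  x <- if (polarity == "dark") -corrected else corrected
  attributes(x) <- list(dim = dim(corrected))
  thr <- otsu_threshold(x)
  fg <- x > thr
  if (!any(fg) || all(fg))
    return(label_mask(matrix(0L, nrow(x), ncol(x))))
  # guard against thresholding pure noise: foreground must stand well
  # clear of the background distribution
  bg_spread <- max(mad(x[!fg]), .Machine$double.eps)
  if (mean(x[fg]) - median(x[!fg]) < 5 * bg_spread)
    return(label_mask(matrix(0L, nrow(x), ncol(x))))
  lab <- cpp_label_components(fg, 4L)
  if (split_touching) {
    edt <- sqrt(cpp_edt_sq(fg))
    markers <- cpp_label_components(edt >= seed_fraction * max(edt), 4L)
    if (max(markers) >= 1L) {
      lab <- cpp_watershed(-edt, markers, fg)
      # pixels unreachable from any seed keep a component label of their own
      orphan <- fg & lab == 0L
      if (any(orphan)) lab[orphan] <- max(lab) +
          cpp_label_components(orphan, 4L)[orphan]
    }
  }
  props <- mask_properties(lab)
  bad <- props$label[props$area_px < min_area_px |
                       props$area_px > max_area_px]
  if (length(bad)) lab[lab %in% bad] <- 0L
  # renumber top-to-bottom
  props <- mask_properties(lab)
  if (nrow(props) > 0) {
    ord <- props$label[order(props$centroid_row)]
    relab <- matrix(0L, nrow(x), ncol(x))
    for (i in seq_along(ord)) relab[lab == ord[i]] <- i
    lab <- relab
  }
  label_mask(lab)
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b logical matrices on the same grid.
#' @return IoU in `[0, 1]`; two empty masks give 0.
#' @export
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}
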