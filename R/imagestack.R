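#' Image stack container
#'
#' An ordered set of 2-D intensity frames sharing dimensions, with channel
#' name, acquisition times and pixel size. The universal raster carrier of
#' the pipeline: phase-contrast time-lapse, fluorescence time-lapse and
#' per-round FISH images are all `image_stack` objects.
#'
#' @param frames list of numeric matrices, all with identical dimensions.
#' @param channel character scalar, e.g. `"phase"`, `"fluor"`, `"Cy3"`.
#' @param times numeric vector of acquisition times in seconds from the
#'   start of the experiment; strictly increasing, one per frame.
#' @param pixel_size physical pixel size in micrometres per pixel.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, channel = "unknown", times = NULL,
                        pixel_size = 0.1) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("`frames` must be a non-empty list of matrices")
  dims <- vapply(frames, function(f) dim(f), integer(2))
  if (!all(dims[1, ] == dims[1, 1]) || !all(dims[2, ] == dims[2, 1]))
    stop("all frames must share dimensions")
  if (is.null(times)) times <- seq_along(frames) - 1
  if (length(times) != length(frames))
    stop("`times` must have one entry per frame")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  structure(
    list(frames = frames, channel = as.character(channel),
         times = as.numeric(times), pixel_size = pixel_size),
    class = "image_stack")
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> channel=%s  %d frame(s) of %dx%d px, %.3g um/px\n",
              x$channel, length(x$frames), d[1], d[2], x$pixel_size))
  invisible(x)
}

#' Crop an image stack to a column interval
#'
#' Trap channels are vertical, so a single trap is a column slice of the
#' full field of view. Intervals are half-open, 0-based: columns
#' `[from, to)`.
#'
#' @param stack an [image_stack].
#' @param interval integer vector `c(from, to)`, half-open 0-based columns.
#' @return An [image_stack] containing the cropped frames.
#' @export
crop_columns <- function(stack, interval) {
  stopifnot(inherits(stack, "image_stack"), length(interval) == 2)
  nc <- ncol(stack$frames[[1]])
  from <- max(0L, as.integer(interval[1]))
  to <- min(nc, as.integer(interval[2]))
  if (to <= from) stop("empty column interval")
  frames <- lapply(stack$frames, function(f) f[, (from + 1):to, drop = FALSE])
  image_stack(frames, stack$channel, stack$times, stack$pixel_size)
}

#' Label mask
#'
#' Integer-labeled segmentation of one frame. Label 0 is background; each
#' positive label is one 4-connected cell; no two cells share a pixel (an
#' integer raster enforces this by construction).
#'
#' @param labels integer matrix of non-negative labels.
#' @param frame_index 0-based index of the frame this mask belongs to.
#' @param check if `TRUE`, verify that each positive label forms a single
#'   4-connected component.
#' @return An integer matrix of class `label_mask` with attribute
#'   `frame_index`.
#' @export
label_mask <- function(labels, frame_index = 0L, check = FALSE) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (any(labels < 0)) stop("labels must be non-negative")
  if (isTRUE(check)) {
    for (l in setdiff(sort(unique(as.vector(labels))), 0L)) {
      cc <- cpp_label_components(labels == l, 4L)
      if (max(cc) > 1L)
        stop(sprintf("label %d is not a single 4-connected component", l))
    }
  }
  structure(labels, frame_index = as.integer(frame_index),
            class = c("label_mask", "matrix", "array"))
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> frame %d: %dx%d px, %d cell(s)\n",
              attr(x, "frame_index"), nrow(x), ncol(x),
              length(setdiff(unique(as.vector(x)), 0L))))
  invisible(x)
}

# Per-label pixel areas and centroids (0-based row/col coordinates).
mask_properties <- function(mask) {
  labs <- setdiff(sort(unique(as.vector(mask))), 0L)
  if (length(labs) == 0L)
    return(data.frame(label = integer(), area_px = integer(),
                      centroid_row = numeric(), centroid_col = numeric()))
  idx <- which(mask > 0)
  lab <- mask[idx]
  r <- (idx - 1) %% nrow(mask)
  c <- (idx - 1) %/% nrow(mask)
  data.frame(
    label = labs,
    area_px = as.integer(tabulate(lab, max(labs))[labs]),
    centroid_row = as.numeric(tapply(r, lab, mean)[as.character(labs)]),
    centroid_col = as.numeric(tapply(c, lab, mean)[as.character(labs)]))
}
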