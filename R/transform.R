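#' Affine transform between camera coordinate frames
#'
#' A 2x2 linear part plus a 2-vector offset mapping fluorescence-camera
#' coordinates (row, col) to phase-contrast-camera coordinates. The linear
#' part must be non-singular.
#'
#' @param A 2x2 numeric matrix, the linear part.
#' @param b numeric length-2 offset.
#' @param rms optional fit residual RMS (set by
#'   [estimate_camera_transform]).
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(A = diag(2), b = c(0, 0), rms = NA_real_) {
  A <- matrix(as.numeric(A), 2, 2)
  if (abs(det(A)) < .Machine$double.eps * 100)
    stop("linear part is singular")
  structure(list(A = A, b = as.numeric(b), rms = rms),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n  A = [",
      sprintf("%.6g", x$A[1, 1]), sprintf("%.6g", x$A[1, 2]), ";",
      sprintf("%.6g", x$A[2, 1]), sprintf("%.6g", x$A[2, 2]), "]\n  b = (",
      sprintf("%.6g", x$b[1]), ",", sprintf("%.6g", x$b[2]), ")",
      if (!is.na(x$rms)) sprintf("  fit RMS = %.4g px", x$rms), "\n")
  invisible(x)
}

#' Apply an affine transform to points
#'
#' @param transform an [affine_transform].
#' @param points n x 2 matrix of (row, col) coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
apply_transform <- function(transform, points) {
  points <- matrix(as.numeric(points), ncol = 2)
  t(transform$A %*% t(points) + transform$b)
}

#' Invert an affine transform
#'
#' @param transform an [affine_transform].
#' @return The inverse [affine_transform].
#' @export
invert_transform <- function(transform) {
  Ai <- solve(transform$A)
  affine_transform(Ai, -as.numeric(Ai %*% transform$b))
}

#' Estimate the inter-camera transform from landmark pairs
#'
#' Least-squares affine fit mapping `points_cam1` onto `points_cam2`,
#' as measured from landmark images captured on the two cameras before the
#' start of an experiment. Exact (machine precision) on noiseless
#' non-degenerate input.
#'
#' @param points_cam1,points_cam2 n x 2 matrices of matched (row, col)
#'   landmark coordinates; n >= 3, not collinear.
#' @return An [affine_transform] with the residual RMS in `$rms`.
#' @export
estimate_camera_transform <- function(points_cam1, points_cam2) {
  p1 <- matrix(as.numeric(points_cam1), ncol = 2)
  p2 <- matrix(as.numeric(points_cam2), ncol = 2)
  if (nrow(p1) != nrow(p2)) stop("point sets must have equal size")
  if (nrow(p1) < 3) stop("at least 3 landmark pairs are required")
  X <- cbind(p1, 1)
  if (qr(X)$rank < 3)
    stop("landmarks are collinear; the affine transform is not identifiable")
  # Solve [p1 1] %*% t(cbind(A, b)) = p2 column-wise
  beta <- qr.solve(X, p2)           # 3 x 2: rows are A[,1], A[,2], b
  A <- t(beta[1:2, , drop = FALSE])
  b <- as.numeric(beta[3, ])
  resid <- X %*% beta - p2
  affine_transform(A, b, rms = sqrt(mean(resid^2)))
}
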