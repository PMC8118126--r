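# In-plane rotation about the image/slice center. The forward transform maps a
# point p = (row, col) to Rot(theta) %*% (p - center) + center, with the angle
# measured in the (col, row) plane; `rotate_matrix` resamples image content
# with the matching inverse map so that `rotate_points` and `rotate_matrix`
# are mutually consistent (a feature drawn at p appears at rotate_points(p)).

deg2rad <- function(d) d * pi / 180

#' Rotate a 2D image about its center
#'
#' @param m numeric or logical matrix (row, col).
#' @param theta rotation angle in degrees (the same convention as
#'   [rotate_points()]).
#' @param method `"bilinear"` for intensities, `"nearest"` for masks.
#' @param fill value used outside the source image.
#' @return matrix of the same dimension and mode as `m`.
#' @keywords internal
rotate_matrix <- function(m, theta, method = c("bilinear", "nearest"), fill = 0) {
  method <- match.arg(method)
  if (theta == 0) return(m)
  logical_in <- is.logical(m)
  mm <- if (logical_in) (m * 1) else m
  nr <- nrow(mm); nc <- ncol(mm)
  ctr_r <- (nr + 1) / 2; ctr_c <- (nc + 1) / 2
  th <- deg2rad(theta)
  co <- cos(th); si <- sin(th)
  rr <- rep(seq_len(nr), times = nc) - ctr_r
  cc <- rep(seq_len(nc), each = nr) - ctr_c
  # inverse map: source = Rot(-theta) %*% dest  (in (col, row) components)
  src_c <- co * cc + si * rr + ctr_c
  src_r <- -si * cc + co * rr + ctr_r
  if (method == "nearest") {
    ri <- round(src_r); ci <- round(src_c)
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- rep(fill, nr * nc)
    v[ok] <- mm[cbind(ri[ok], ci[ok])]
  } else {
    v <- bilinear_sample(mm, src_r, src_c)
    outside <- src_r < 1 | src_r > nr | src_c < 1 | src_c > nc
    v[outside] <- fill
  }
  out <- matrix(v, nr, nc)
  if (logical_in) out > 0.5 else out
}

#' Rotate (row, col) points about an image center
#'
#' Forward analytic transform matching [rotate_matrix()]: content rotated by
#' `theta` moves a source point to the returned location.
#'
#' @param pts two-column matrix of (row, col) positions.
#' @param theta angle in degrees.
#' @param dim image dimension `c(nrow, ncol)` defining the center.
#' @return two-column matrix of rotated (row, col) positions.
#' @keywords internal
rotate_points <- function(pts, theta, dim) {
  if (theta == 0) return(pts)
  ctr_r <- (dim[1] + 1) / 2; ctr_c <- (dim[2] + 1) / 2
  th <- deg2rad(theta)
  co <- cos(th); si <- sin(th)
  r <- pts[, 1] - ctr_r; c <- pts[, 2] - ctr_c
  cbind(row = si * c + co * r + ctr_r,
        col = co * c - si * r + ctr_c)
}
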