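#' Estimate the in-plane head angle of a volume
#'
#' Stage 1 of the midline pipeline. A bilaterally symmetric slice equals its
#' reflection about the symmetry axis, so the head angle is found by
#' reflecting the middle slice over the vertical axis, rotating the
#' reflection by `2 * theta` for each candidate angle on a \[-20, 20\] degree
#' grid with 0.5 degree steps, and maximizing the normalized cross-correlation
#' with the original slice (computed over the union of the two brain masks,
#' which removes brightness bias). Ties are broken toward the smaller
#' `|theta|`. Near-circular heads can produce an essentially flat score
#' curve; when the score range falls below 1% of the maximum the estimate is
#' forced to 0 with a warning, since any angle is then equally supported.
#'
#' @param vol a [flair_volume()].
#' @param theta_min,theta_max,theta_step candidate grid in degrees.
#' @param angle_slice `"middle"` or an explicit slice index.
#' @return object of class `head_angle`: `theta_hat` (degrees), `grid`,
#'   `score` (normalized cross-correlation per candidate) and `slice_index`.
#' @export
estimate_head_angle <- function(vol, theta_min = -20, theta_max = 20,
                                theta_step = 0.5, angle_slice = "middle") {
  S <- dim(vol$data)[1]
  s <- if (identical(angle_slice, "middle")) (S + 1L) %/% 2L else as.integer(angle_slice)
  msk <- vol$mask[s, , ]
  if (!any(msk)) stop(sprintf("brain mask is empty on angle slice %d", s))
  img <- vol$data[s, , ]
  refl <- img[, rev(seq_len(ncol(img))), drop = FALSE]
  refl_m <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
  grid <- seq(theta_min, theta_max, by = theta_step)
  score <- vapply(grid, function(th) {
    rr <- rotate_matrix(refl, 2 * th, "bilinear")
    rm <- rotate_matrix(refl_m, 2 * th, "nearest")
    sel <- msk | rm
    if (sum(sel) < 3) return(NA_real_)
    suppressWarnings(cor(img[sel], rr[sel]))
  }, numeric(1))
  ord <- order(abs(grid), grid)      # smallest |theta| first for tie-breaks
  best <- ord[which.max(score[ord])]
  theta_hat <- grid[best]
  rng <- diff(range(score, na.rm = TRUE))
  if (!is.finite(rng) || rng < 0.01 * max(abs(score), na.rm = TRUE)) {
    warning("flat cross-correlation score (near-circular head?): forcing theta = 0")
    theta_hat <- 0
  } else if (abs(theta_hat) >= theta_max) {
    warning(sprintf("head angle estimate %.1f lies on the search-grid boundary", theta_hat))
  }
  structure(list(theta_hat = theta_hat, grid = grid, score = score,
                 slice_index = s),
            class = "head_angle")
}

#' @export
print.head_angle <- function(x, ...) {
  cat(sprintf("<head_angle> theta_hat = %.1f deg (slice %d, grid %g..%g by %g)\n",
              x$theta_hat, x$slice_index, min(x$grid), max(x$grid),
              x$grid[2] - x$grid[1]))
  invisible(x)
}

#' Rotate a volume in-plane
#'
#' Rotates every slice by `theta` degrees about the image center (bilinear
#' interpolation for intensities, nearest-neighbor for the mask). To correct
#' an estimated head angle `theta_hat`, rotate by `-theta_hat`.
#'
#' @param vol a [flair_volume()].
#' @param theta rotation in degrees; `|theta| <= 45`.
#' @return rotated [flair_volume()].
#' @export
rotate_volume <- function(vol, theta) {
  if (abs(theta) > 45) stop("|theta| must be <= 45 degrees")
  if (theta == 0) return(vol)
  out <- vol
  for (s in seq_len(dim(vol$data)[1])) {
    out$data[s, , ] <- rotate_matrix(vol$data[s, , ], theta, "bilinear")
    out$mask[s, , ] <- rotate_matrix(vol$mask[s, , ], theta, "nearest")
  }
  out
}
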