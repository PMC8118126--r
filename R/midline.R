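# Stage 3: midline generation and hemispheric separation.

#' Fit a slice midline from its control points
#'
#' Shape-preserving piecewise-cubic (monotone Hermite) interpolation through
#' the control points, sampled at every row of their span, followed by a
#' least-squares cubic polynomial over the samples; the polynomial is the
#' final smooth representation and extrapolates beyond the control-point
#' span. With fewer than 4 points the polynomial degree drops to
#' `n - 1` (a single point yields a vertical line).
#'
#' @param points matrix with columns (row, col) of control points.
#' @param rows_eval row indices at which to evaluate the midline.
#' @param ncols number of image columns (evaluated curve is clipped inside).
#' @return list with `m` (columns at `rows_eval`), `coef` (length-4
#'   polynomial coefficients in the 0-based row offset), `rows` (`rows_eval`).
#' @export
fit_slice_midline <- function(points, rows_eval, ncols = Inf) {
  if (is.null(points) || nrow(points) == 0) stop("no control points for slice")
  ord <- order(points[, 1])
  r <- points[ord, 1]; c <- points[ord, 2]
  n <- length(r)
  if (n == 1) {
    cf <- c(c[1], 0, 0, 0)
  } else {
    f <- splinefun(r, c, method = "monoH.FC")
    rs <- seq(floor(r[1]), ceiling(r[n]))
    cs <- f(rs)
    deg <- min(3L, n - 1L)
    X <- outer(rs - 1, 0:deg, `^`)
    cf <- qr.solve(X, cs)
    cf <- c(cf, rep(0, 4 - length(cf)))
  }
  m <- polyval0(cf, rows_eval - 1)
  if (is.finite(ncols)) m <- clip(m, 1, ncols)
  list(m = m, coef = cf, rows = rows_eval)
}

#' Split a volume into hemisphere masks
#'
#' Applies the half-open rule per voxel: a voxel with column strictly below
#' the midline column of its row is left, otherwise right. When a head-angle
#' correction of `theta_used` degrees was applied, each native brain voxel is
#' mapped into the corrected frame analytically and classified there, which
#' keeps the native masks an exact partition of the native brain mask.
#'
#' @param vol a [flair_volume()] in the native frame.
#' @param midlines list (one per slice) of `fit_slice_midline()` results in
#'   the corrected frame; slices with `NULL` entries inherit the nearest
#'   non-missing slice's midline.
#' @param theta_used head-angle correction (degrees) that produced the
#'   corrected frame; 0 when none.
#' @return object of class `hemisphere_pair`: logical arrays `left`,
#'   `right`, and `frame = "native"`.
#' @export
separate_hemispheres <- function(vol, midlines, theta_used = 0) {
  d <- dim(vol$data); S <- d[1]
  have <- which(!vapply(midlines, is.null, logical(1)))
  if (length(have) == 0) stop("no midline available for any slice")
  nearest <- vapply(seq_len(S), function(s) have[which.min(abs(have - s))], integer(1))
  left <- array(FALSE, d); right <- array(FALSE, d)
  for (s in seq_len(S)) {
    ml <- midlines[[nearest[s]]]
    idx <- which(vol$mask[s, , ], arr.ind = TRUE)
    if (nrow(idx) == 0) next
    pos <- if (theta_used != 0) rotate_points(idx, -theta_used, d[2:3]) else idx
    mcol <- polyval0(ml$coef, pos[, 1] - 1)
    is_left <- pos[, 2] < mcol
    lsl <- matrix(FALSE, d[2], d[3]); rsl <- matrix(FALSE, d[2], d[3])
    lsl[idx[is_left, , drop = FALSE]] <- TRUE
    rsl[idx[!is_left, , drop = FALSE]] <- TRUE
    left[s, , ] <- lsl; right[s, , ] <- rsl
  }
  structure(list(left = left, right = right, frame = "native"),
            class = "hemisphere_pair")
}

#' Estimate the mid-sagittal surface of a volume
#'
#' End-to-end orchestrator: head-angle estimation and correction,
#' control-point estimation with septum handling, cross-slice robust repair,
#' per-slice cubic midline fitting, and hemispheric separation mapped back to
#' the native frame. Deterministic: two runs on the same input produce
#' identical masks.
#'
#' @param vol a [flair_volume()].
#' @param config a [default_config()] list.
#' @return object of class `midline_result`: `midlines` (per-slice fits in
#'   the corrected frame), `native_points` (per-slice (row, col) midline
#'   samples in the native frame), `hemispheres` (a `hemisphere_pair`),
#'   `head_angle`, `grid` (the repaired `control_point_grid`), `cerebral`,
#'   `theta_used` and the input `spacing`.
#' @export
estimate_volume_midline <- function(vol, config = default_config()) {
  ha <- estimate_head_angle(vol, config$theta_min, config$theta_max,
                            config$theta_step, config$angle_slice)
  theta <- ha$theta_hat
  vol_c <- if (theta != 0) rotate_volume(vol, -theta) else vol
  grid <- estimate_control_points(vol_c, config)
  grid <- refine_across_slices(grid, config$mad_k)
  d <- dim(vol$data); S <- d[1]
  midlines <- vector("list", S)
  fallback <- median(grid$col, na.rm = TRUE)
  for (s in which(grid$cerebral)) {
    ok <- which(!is.na(grid$col[s, ]))
    rows_s <- which(apply(vol_c$mask[s, , ], 1, any))
    if (length(rows_s) == 0) next
    if (length(ok) == 0) {
      warning(sprintf("no control points on slice %d; using volume-median midline", s))
      midlines[[s]] <- list(m = rep(fallback, length(rows_s)),
                            coef = c(fallback, 0, 0, 0), rows = rows_s)
    } else {
      pts <- cbind(grid$row[s, ok], grid$col[s, ok])
      midlines[[s]] <- fit_slice_midline(pts, rows_s, d[3])
    }
  }
  hemis <- separate_hemispheres(vol, midlines, theta_used = theta)
  native_points <- vector("list", S)
  for (s in seq_len(S)) {
    ml <- midlines[[s]]
    if (is.null(ml)) next
    pts <- cbind(ml$rows, ml$m)
    native_points[[s]] <- if (theta != 0) rotate_points(pts, theta, d[2:3]) else pts
    colnames(native_points[[s]]) <- c("row", "col")
  }
  structure(list(midlines = midlines, native_points = native_points,
                 hemispheres = hemis, head_angle = ha, grid = grid,
                 cerebral = grid$cerebral, theta_used = theta,
                 spacing = vol$spacing),
            class = "midline_result")
}

#' @export
print.midline_result <- function(x, ...) {
  cat(sprintf("<midline_result> %d slices (%d cerebral), theta_used = %.1f deg\n",
              length(x$midlines), sum(x$cerebral), x$theta_used))
  invisible(x)
}

#' Per-slice midline summary as a tibble
#'
#' @param x a `midline_result`.
#' @param ... unused.
#' @return tibble with `slice`, `cerebral`, `n_points`, `n_repaired`,
#'   and the fitted polynomial coefficients `p0..p3`.
#' @export
tidy.midline_result <- function(x, ...) {
  S <- length(x$midlines)
  cf <- t(vapply(seq_len(S), function(s) {
    if (is.null(x$midlines[[s]])) rep(NA_real_, 4) else x$midlines[[s]]$coef
  }, numeric(4)))
  tibble(slice = seq_len(S), cerebral = x$cerebral,
         n_points = rowSums(!is.na(x$grid$col)),
         n_repaired = rowSums(x$grid$flag == "repaired"),
         p0 = cf[, 1], p1 = cf[, 2], p2 = cf[, 3], p3 = cf[, 4])
}

#' Write midline results to disk
#'
#' Hemisphere masks as NIfTI, the native-frame midline as a (slice, row, col)
#' CSV, and the per-slice polynomial coefficients plus head angle as JSON.
#'
#' @param result a `midline_result`.
#' @param vol the input [flair_volume()] (for spacing/geometry).
#' @param dir output directory.
#' @param stem file stem.
#' @return invisibly, named vector of written paths.
#' @export
write_midline_result <- function(result, vol, dir, stem = "subject") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(left = file.path(dir, paste0(stem, "_left.nii.gz")),
             right = file.path(dir, paste0(stem, "_right.nii.gz")),
             midline_csv = file.path(dir, paste0(stem, "_midline.csv")),
             midline_json = file.path(dir, paste0(stem, "_midline.json")))
  put <- function(arr, p) {
    img <- RNifti::asNifti(aperm(arr * 1, c(3, 2, 1)))
    RNifti::pixdim(img) <- rev(vol$spacing)
    RNifti::writeNifti(img, p, datatype = "uint8")
  }
  put(result$hemispheres$left, paths[["left"]])
  put(result$hemispheres$right, paths[["right"]])
  pts <- do.call(rbind, lapply(seq_along(result$native_points), function(s) {
    p <- result$native_points[[s]]
    if (is.null(p)) return(NULL)
    data.frame(slice = s, row = p[, 1], col = p[, 2])
  }))
  write.csv(pts, paths[["midline_csv"]], row.names = FALSE)
  cf <- lapply(result$midlines, function(m) if (is.null(m)) NULL else m$coef)
  jsonlite::write_json(list(theta_used = result$theta_used, poly = cf),
                       paths[["midline_json"]], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
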