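# Validation metrics comparing an estimated midline / hemisphere split to
# ground truth: mean Hausdorff distance (px), mean absolute distance (mm),
# and per-hemisphere volume difference (mL).

#' Mean Hausdorff distance between two point sets
#'
#' For every point of one set the Euclidean distance to the nearest point of
#' the other; the two directed distance vectors are concatenated and
#' averaged. Symmetric by construction, zero iff the sets are equal as sets,
#' and never larger than the classical max-Hausdorff distance. Computed in
#' (isotropic) pixel units; pass mm-scaled coordinates for physical units.
#'
#' @param L1,L2 two-column matrices of (row, col) points.
#' @return mean of the minimum distances.
#' @export
mean_hausdorff <- function(L1, L2) {
  L1 <- as.matrix(L1); L2 <- as.matrix(L2)
  if (nrow(L1) == 0 || nrow(L2) == 0) stop("point sets must be non-empty")
  D2 <- outer(L1[, 1], L2[, 1], `-`)^2 + outer(L1[, 2], L2[, 2], `-`)^2
  d12 <- sqrt(apply(D2, 1, min))
  d21 <- sqrt(apply(D2, 2, min))
  mean(c(d12, d21))
}

#' Mean absolute distance between two midline column vectors
#'
#' Pixel-by-pixel comparison of the midline columns of a slice, converted to
#' mm via the in-plane column spacing.
#'
#' @param y1,y2 midline column positions at matching rows (equal length).
#' @param dx_mm in-plane column spacing in mm.
#' @return mean absolute distance in mm.
#' @export
mean_absolute_distance <- function(y1, y2, dx_mm = 1) {
  if (length(y1) != length(y2)) {
    stop(sprintf("length mismatch: %d vs %d", length(y1), length(y2)))
  }
  mean(abs(y1 - y2)) * dx_mm
}

#' Hemispheric volume difference
#'
#' Absolute voxel-count difference per hemisphere, converted to mL.
#'
#' @param auto,truth `hemisphere_pair` objects on the same grid.
#' @param spacing voxel spacing `c(dz, dy, dx)` in mm.
#' @return named numeric `c(dv_left, dv_right)` in mL.
#' @export
volume_difference <- function(auto, truth, spacing) {
  if (!identical(dim(auto$left), dim(truth$left))) {
    stop(sprintf("grid mismatch: %s vs %s",
                 paste(dim(auto$left), collapse = "x"),
                 paste(dim(truth$left), collapse = "x")))
  }
  vv <- prod(spacing) / 1000
  c(dv_left = abs(sum(auto$left) - sum(truth$left)) * vv,
    dv_right = abs(sum(auto$right) - sum(truth$right)) * vv)
}

#' Read a ground-truth midline from CSV
#'
#' Accepts the per-slice `(slice, row, col)` CSV written by [write_phantom()]
#' or produced by manual delineation.
#'
#' @param path CSV file with columns `slice`, `row`, `col`.
#' @return list of per-slice two-column (row, col) matrices.
#' @export
read_midline_csv <- function(path) {
  df <- read.csv(path)
  need <- c("slice", "row", "col")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("midline CSV missing columns: ", paste(miss, collapse = ", "))
  out <- vector("list", max(df$slice))
  for (s in unique(df$slice)) {
    sub <- df[df$slice == s, ]
    out[[s]] <- cbind(row = sub$row, col = sub$col)
  }
  out
}

#' Evaluate an estimated midline against phantom truth
#'
#' Computes the three validation metrics per volume: mean Hausdorff distance
#' between native-frame midline point sets (px), mean absolute distance
#' between the corrected-frame midline and the analytic fissure curve,
#' averaged over cerebral slices (reported in px and mm), and hemispheric
#' volume differences (mL).
#'
#' @param result a `midline_result`.
#' @param truth a `phantom_truth`.
#' @param spacing voxel spacing `c(dz, dy, dx)` in mm.
#' @return one-row tibble: `mean_hd_px`, `mad_px`, `mad_mm`, `dv_left_ml`,
#'   `dv_right_ml`.
#' @export
evaluate_midline <- function(result, truth, spacing) {
  S <- length(result$midlines)
  hd <- mad_px <- rep(NA_real_, S)
  for (s in seq_len(S)) {
    ml <- result$midlines[[s]]
    if (is.null(ml) || !result$cerebral[s]) next
    est <- result$native_points[[s]]
    hd[s] <- mean_hausdorff(est, truth$midline[[s]])
    ct <- polyval0(truth$poly[s, ], ml$rows - 1)
    mad_px[s] <- mean(abs(ml$m - ct))
  }
  dv <- volume_difference(result$hemispheres,
                          list(left = truth$left, right = truth$right), spacing)
  tibble(mean_hd_px = mean(hd, na.rm = TRUE),
         mad_px = mean(mad_px, na.rm = TRUE),
         mad_mm = mean(mad_px, na.rm = TRUE) * spacing[3],
         dv_left_ml = dv[["dv_left"]], dv_right_ml = dv[["dv_right"]])
}
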