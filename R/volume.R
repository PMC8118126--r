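#' Construct a FLAIR volume object
#'
#' Container for a brain-extracted, intensity-standardized axial volume.
#' Arrays are indexed `[slice, row, col]`; rows run top to bottom of the image
#' and columns left to right. On the standardized intensity scale CSF sits
#' below 200, normal-appearing brain matter (NABM) in \[200, 400\] and lesions
#' above 400.
#'
#' @param data 3D numeric array `[slice, row, col]` of standardized intensities.
#' @param spacing voxel spacing `c(dz, dy, dx)` in mm (slice thickness first).
#' @param mask logical 3D array of the same dimension marking brain voxels;
#'   defaults to `data > 0`.
#' @param meta optional list of provenance fields (`source`, ...).
#' @return object of class `flair_volume`.
#' @export
flair_volume <- function(data, spacing, mask = NULL, meta = list()) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array [slice, row, col]")
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive mm values (dz, dy, dx)")
  }
  if (any(!is.finite(data))) stop("`data` contains non-finite values")
  if (is.null(mask)) mask <- data > 0
  if (!identical(dim(mask), dim(data))) {
    stop(sprintf("grid mismatch: mask %s vs data %s",
                 paste(dim(mask), collapse = "x"), paste(dim(data), collapse = "x")))
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 mask = array(as.logical(mask), dim(mask)),
                 meta = c(meta, list(axes = "slice-row-col"))),
            class = "flair_volume")
}

#' @export
print.flair_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<flair_volume> %d slices x %d rows x %d cols, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  brain voxels: %d (%.1f%%), intensity range %.1f..%.1f\n",
              sum(x$mask), 100 * mean(x$mask),
              min(x$data[x$mask]), max(x$data[x$mask])))
  invisible(x)
}

#' Load a NIfTI volume and brain mask
#'
#' Reads an axial NIfTI volume and its binary brain mask and reorders the
#' arrays to the package convention `[slice, row, col]` (the NIfTI fastest
#' axis is taken as image columns, the slowest as the axial slice axis).
#'
#' @param path NIfTI file (optionally gzipped) with the intensity volume.
#' @param mask_path NIfTI file with the binary brain mask on the same grid.
#' @return a [flair_volume()].
#' @export
load_volume <- function(path, mask_path) {
  img <- RNifti::readNifti(path)
  msk <- RNifti::readNifti(mask_path)
  a <- as.array(img); m <- as.array(msk)
  if (length(dim(a)) != 3L) stop("expected a 3D axial acquisition, got ", length(dim(a)), "D")
  if (!identical(dim(a), dim(m))) {
    stop(sprintf("grid mismatch: volume %s vs mask %s",
                 paste(dim(a), collapse = "x"), paste(dim(m), collapse = "x")))
  }
  pd <- RNifti::pixdim(img)[1:3]
  data <- aperm(a, c(3, 2, 1))
  mask <- aperm(m, c(3, 2, 1)) > 0.5
  flair_volume(data, spacing = rev(pd), mask = mask,
               meta = list(source = path))
}

#' Write a volume (and optionally its mask) as NIfTI
#'
#' @param vol a [flair_volume()].
#' @param path output NIfTI path for the intensities.
#' @param mask_path optional output path for the brain mask.
#' @return invisibly, `path`.
#' @export
write_volume <- function(vol, path, mask_path = NULL) {
  put <- function(arr, p) {
    img <- RNifti::asNifti(aperm(arr, c(3, 2, 1)))
    RNifti::pixdim(img) <- rev(vol$spacing)
    RNifti::writeNifti(img, p, datatype = "double")
  }
  put(vol$data, path)
  if (!is.null(mask_path)) put(vol$mask * 1, mask_path)
  invisible(path)
}

#' Linearly rescale intensities to the standardized band
#'
#' Simple affine stand-in for a full multi-center standardization pipeline:
#' maps the 1st/99th intensity percentiles inside the brain mask onto
#' `target_band`, so that with the default band (100, 450) CSF lands below the
#' 200 threshold and NABM near 300.
#'
#' @param vol a [flair_volume()].
#' @param target_band `c(low, high)` standardized intensities for the 1st and
#'   99th brain percentiles.
#' @return rescaled [flair_volume()].
#' @export
rescale_to_standard <- function(vol, target_band = c(100, 450)) {
  if (!any(vol$mask)) stop("brain mask is empty")
  q <- quantile(vol$data[vol$mask], c(0.01, 0.99), names = FALSE)
  if (diff(q) <= 0) stop("constant image: cannot rescale")
  slope <- diff(target_band) / diff(q)
  out <- vol
  out$data <- target_band[1] + (vol$data - q[1]) * slope
  out
}

# 2D separable linear interpolation of matrix `m` at output row/col center
# positions (vectors of fractional source indices); clamped at the border.
interp2_lin <- function(m, rout, cout) {
  nr <- nrow(m); nc <- ncol(m)
  r <- clip(rout, 1, nr); c <- clip(cout, 1, nc)
  r0 <- pmin(floor(r), nr - 1L); r0[nr == 1] <- 1L
  c0 <- pmin(floor(c), nc - 1L); c0[nc == 1] <- 1L
  fr <- r - r0; fc <- c - c0
  if (nr == 1L) { r0 <- rep(1L, length(r)); fr <- rep(0, length(r)) }
  if (nc == 1L) { c0 <- rep(1L, length(c)); fc <- rep(0, length(c)) }
  m00 <- m[r0, c0, drop = FALSE]
  m10 <- m[pmin(r0 + 1L, nr), c0, drop = FALSE]
  m01 <- m[r0, pmin(c0 + 1L, nc), drop = FALSE]
  m11 <- m[pmin(r0 + 1L, nr), pmin(c0 + 1L, nc), drop = FALSE]
  wr <- matrix(fr, length(r), length(c))
  wc <- matrix(fc, length(r), length(c), byrow = TRUE)
  m00 * (1 - wr) * (1 - wc) + m10 * wr * (1 - wc) +
    m01 * (1 - wr) * wc + m11 * wr * wc
}

interp2_nn <- function(m, rout, cout) {
  ri <- clip(round(rout), 1, nrow(m))
  ci <- clip(round(cout), 1, ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Resample a volume to a new voxel spacing
#'
#' In-plane intensities are linearly interpolated and the brain mask is
#' resampled nearest-neighbor; the slice axis uses nearest-neighbor slice
#' selection. Physical extent is preserved to within one voxel. Used to put
#' cohorts on a common grid (default biomarker grid: 0.35 x 0.35 mm in-plane,
#' 3 mm slices) before texture analysis.
#'
#' @param vol a [flair_volume()].
#' @param new_spacing target `c(dz, dy, dx)` in mm.
#' @return resampled [flair_volume()].
#' @export
resample_volume <- function(vol, new_spacing) {
  if (any(new_spacing <= 0)) stop("`new_spacing` must be strictly positive")
  d <- dim(vol$data); sp <- vol$spacing
  nd <- pmax(1L, round(d * sp / new_spacing))
  if (all(nd == d) && isTRUE(all.equal(sp, as.numeric(new_spacing)))) return(vol)
  # voxel-center mapping preserving the physical field of view
  src_pos <- function(n_new, sp_new, sp_old) ((seq_len(n_new) - 0.5) * sp_new) / sp_old + 0.5
  zs <- clip(round(src_pos(nd[1], new_spacing[1], sp[1])), 1, d[1])
  rs <- src_pos(nd[2], new_spacing[2], sp[2])
  cs <- src_pos(nd[3], new_spacing[3], sp[3])
  data <- array(0, nd); mask <- array(FALSE, nd)
  for (k in seq_len(nd[1])) {
    data[k, , ] <- interp2_lin(vol$data[zs[k], , ], rs, cs)
    mask[k, , ] <- interp2_nn(vol$mask[zs[k], , ] * 1L, rs, cs) > 0.5
  }
  flair_volume(data, spacing = as.numeric(new_spacing), mask = mask, meta = vol$meta)
}

#' CSF load of a standardized volume
#'
#' Counts brain-mask voxels below the CSF threshold on the standardized scale
#' and converts to milliliters; used as a simple disease-burden covariate.
#'
#' @param vol a [flair_volume()].
#' @param threshold CSF intensity threshold (default 200; strict `<`).
#' @return CSF volume in mL.
#' @export
compute_csf_load <- function(vol, threshold = 200) {
  n <- sum(vol$mask & vol$data < threshold)
  n * prod(vol$spacing) / 1000
}

#' Hemispheric volumes in milliliters
#'
#' @param hemis a `hemisphere_pair` (see [separate_hemispheres()]).
#' @param spacing voxel spacing `c(dz, dy, dx)` in mm.
#' @return named numeric `c(v_left, v_right)` in mL.
#' @export
hemisphere_volumes <- function(hemis, spacing) {
  vv <- prod(spacing) / 1000
  c(v_left = sum(hemis$left) * vv, v_right = sum(hemis$right) * vv)
}
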