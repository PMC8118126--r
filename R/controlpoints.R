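# Stage 2: per-slice control-point estimation inside a 2 cm midline band.
# Each 2 x 2 cm ROI casts up to eight feature votes (intensity profiles,
# gradient valley, Gabor energy, mirrored symmetry); the lower median of the
# votes is the ROI's control point. A CSF-dominated ROI (> 50% below the CSF
# threshold, i.e. ventricles around the septum pellucidum) is intensity
# inverted first so the bright septum becomes the dark line the features look
# for. A 3-scaled-MAD rule across slices repairs stray points afterwards.

#' Default pipeline configuration
#'
#' All tunable parameters of the midline pipeline with the method's stated
#' defaults: \eqn{\pm 20}{+-20} degree / 0.5 degree head-angle grid, 2 cm ROI,
#' CSF threshold 200, NABM band \[200, 400\], 3-scaled-MAD repair, z-cut 3,
#' LBP radius 3 with 8 neighbors, biomarker grid 0.35 x 0.35 x 3 mm.
#'
#' @param ... named overrides of any default.
#' @return named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(theta_min = -20, theta_max = 20, theta_step = 0.5,
              angle_slice = "middle",
              roi_mm = 20, csf_threshold = 200, nabm_band = c(200, 400),
              mse_vote = "min", gabor_vote = "min", mad_k = 3,
              cerebral_slice_fraction = 0.5,
              standard_band = c(100, 450),
              biomarker_spacing = c(3, 0.35, 0.35),
              lbp_radius = 3, lbp_neighbors = 8, glcm_levels = 32,
              z_cut = 3)
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

#' Locate the 2 cm midline band of a slice
#'
#' @param ncols number of image columns.
#' @param dx in-plane column spacing in mm.
#' @param roi_mm band width in mm (default 20).
#' @return integer vector of column indices (half-open band of width
#'   `round(roi_mm / dx)` centered on the middle column).
#' @export
extract_midline_band <- function(ncols, dx, roi_mm = 20) {
  w <- round(roi_mm / dx)
  if (ncols < w) stop(sprintf("image (%d cols) narrower than the %g mm band (%d px)", ncols, roi_mm, w))
  center0 <- ncols %/% 2L                  # 0-based middle column
  lo0 <- center0 - w %/% 2L
  lo0 <- max(0L, min(lo0, ncols - w))      # clip to the image
  (lo0 + 1L):(lo0 + w)
}

#' Partition the brain rows of a slice into 2 cm ROI windows
#'
#' Windows of height `round(roi_mm / dy)` pixels start at the first brain-mask
#' row and step by the window height down to the last brain row; a final
#' partial window is kept if it spans at least half a window, otherwise it is
#' merged into the previous one.
#'
#' @param slice_mask logical matrix (row, col) brain mask of the slice.
#' @param dy in-plane row spacing in mm.
#' @param roi_mm window size in mm.
#' @return list of integer vectors `c(r_first, r_last)` (inclusive); empty
#'   list for an empty mask.
#' @export
partition_rois <- function(slice_mask, dy, roi_mm = 20) {
  h <- round(roi_mm / dy)
  brain_rows <- which(apply(slice_mask, 1, any))
  if (length(brain_rows) == 0) return(list())
  r0 <- brain_rows[1]; r1 <- brain_rows[length(brain_rows)]
  starts <- seq(r0, r1, by = h)
  wins <- lapply(starts, function(a) c(a, min(a + h - 1L, r1)))
  if (length(wins) > 1) {
    last <- wins[[length(wins)]]
    if (diff(last) + 1 < h / 2) {
      wins[[length(wins) - 1]][2] <- last[2]
      wins[[length(wins)]] <- NULL
    }
  }
  wins
}

# CSF fraction of a ROI and septum-pellucidum inversion. Returns the possibly
# inverted pixel patch plus the inversion flag; patches with no brain pixels
# return NULL (the ROI casts no votes).
invert_if_csf <- function(pixels, maskp, csf_threshold = 200) {
  if (!any(maskp)) return(NULL)
  frac <- mean(pixels[maskp] < csf_threshold)
  inverted <- frac > 0.5
  if (inverted) pixels <- max(pixels[maskp]) - pixels
  list(pixels = pixels, inverted = inverted, csf_fraction = frac)
}

# per-column statistics over brain pixels; columns without brain pixels get NA
col_profiles <- function(pixels, maskp) {
  n <- colSums(maskp)
  px <- pixels; px[!maskp] <- 0
  s <- colSums(px)
  e <- colSums(px^2)
  list(n = n, sum = ifelse(n > 0, s, NA), energy = ifelse(n > 0, e, NA),
       rms = ifelse(n > 0, sqrt(e / pmax(n, 1)), NA))
}

vote <- function(name, j, cols, profile) {
  if (is.na(j)) return(NULL)
  list(feature = name, col = cols[j], local = j, profile = profile)
}

#' Intensity-profile feature votes of a ROI
#'
#' Per-column intensity sum, energy and RMS vote their minimum (CSF is dark
#' in FLAIR); cumulative energy votes the column where the running sum of
#' column energies first reaches half the ROI total (the energy-balance
#' column, which is the exact center for a mirror-symmetric ROI).
#'
#' @param pixels,maskp ROI intensity and brain-mask patches.
#' @param cols absolute column indices of the ROI.
#' @return list of up to 4 votes (`int_sum`, `int_energy`, `int_rms`,
#'   `cum_energy`), each with the absolute `col` and its `profile`.
#' @export
column_profile_features <- function(pixels, maskp, cols) {
  pr <- col_profiles(pixels, maskp)
  votes <- list(
    vote("int_sum", which.min(pr$sum), cols, pr$sum),
    vote("int_energy", which.min(pr$energy), cols, pr$energy),
    vote("int_rms", which.min(pr$rms), cols, pr$rms))
  tot <- sum(pr$energy, na.rm = TRUE)
  if (tot > 0) {
    cs <- cumsum(ifelse(is.na(pr$energy), 0, pr$energy))
    j <- which(cs >= tot / 2)[1]
    votes <- c(votes, list(vote("cum_energy", j, cols, cs / tot)))
  }
  Filter(Negate(is.null), votes)
}

#' Gradient-valley feature vote of a ROI
#'
#' The fissure lies between the two strong gradient edges of its walls with a
#' low gradient in between. The per-column mean gradient magnitude (over
#' brain pixels) is scanned for its two highest local peaks at least 3 px
#' apart; the vote is the profile minimum strictly between them. With fewer
#' than two peaks the global minimum is voted.
#'
#' @inheritParams column_profile_features
#' @return a single vote (`grad_valley`) or `NULL`.
#' @export
gradient_valley_feature <- function(pixels, maskp, cols) {
  if (ncol(pixels) < 3) return(NULL)
  G <- grad_mag(pixels)
  n <- colSums(maskp)
  Gm <- G; Gm[!maskp] <- 0
  prof <- ifelse(n > 0, colSums(Gm) / pmax(n, 1), NA)
  W <- length(prof)
  # strict local maxima (flat profiles yield none)
  is_peak <- rep(FALSE, W)
  for (j in 2:(W - 1)) {
    if (!is.na(prof[j]) && !is.na(prof[j - 1]) && !is.na(prof[j + 1]) &&
        prof[j] >= prof[j - 1] && prof[j] >= prof[j + 1] &&
        (prof[j] > prof[j - 1] || prof[j] > prof[j + 1])) {
      is_peak[j] <- TRUE
    }
  }
  peaks <- which(is_peak)[order(prof[is_peak], decreasing = TRUE)]
  j <- NA_integer_
  if (length(peaks) >= 2) {
    p1 <- peaks[1]
    p2 <- peaks[abs(peaks - p1) >= 3][1]
    if (!is.na(p2)) {
      lo <- min(p1, p2); hi <- max(p1, p2)
      if (hi - lo >= 2) {
        inner <- (lo + 1):(hi - 1)
        j <- inner[which.min(prof[inner])]
      }
    }
  }
  if (is.na(j)) j <- which.min(prof)
  vote("grad_valley", j, cols, prof)
}

# cached Gabor bank: 4 orientations x wavelengths, quadrature pairs, DC-free
gabor_bank <- function(wavelengths = c(4, 8), orientations = c(0, 45, 90, 135)) {
  bank <- list()
  for (lam in wavelengths) {
    sig <- 0.5 * lam
    half <- ceiling(1.5 * sig)
    xs <- -half:half
    X <- matrix(xs, length(xs), length(xs), byrow = TRUE)   # col offset
    Y <- matrix(xs, length(xs), length(xs))                 # row offset
    for (th in orientations) {
      a <- deg2rad(th)
      xr <- X * cos(a) + Y * sin(a)
      yr <- -X * sin(a) + Y * cos(a)
      env <- exp(-(xr^2 + 0.25 * yr^2) / (2 * sig^2))
      even <- env * cos(2 * pi * xr / lam)
      odd <- env * sin(2 * pi * xr / lam)
      even <- even - mean(even)      # zero DC: constant patches respond 0
      bank[[length(bank) + 1]] <- list(even = even, odd = odd, size = 2 * half + 1)
    }
  }
  bank
}

the_gabor_bank <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- gabor_bank()
    cache
  }
})

#' Gabor texture-energy feature vote of a ROI
#'
#' Energy of a small Gabor bank (4 orientations, wavelengths 4 and 8 px,
#' sigma tied to wavelength, quadrature pairs). Homogeneous CSF produces low
#' energy, textured brain matter high energy, so the default vote is the
#' column of minimum mean energy; `vote = "max"` selects the opposite
#' polarity. Wavelengths whose kernel support exceeds the ROI are skipped;
#' if none fit, no vote is cast.
#'
#' @inheritParams column_profile_features
#' @param vote_rule `"min"` (default) or `"max"`.
#' @return a single vote (`gabor_energy`) or `NULL`.
#' @export
gabor_energy_feature <- function(pixels, maskp, cols, vote_rule = "min") {
  bank <- the_gabor_bank()
  usable <- Filter(function(b) b$size <= min(dim(pixels)), bank)
  if (length(usable) == 0) return(NULL)
  E <- matrix(0, nrow(pixels), ncol(pixels))
  for (b in usable) {
    # replicate padding: a constant ROI then responds exactly 0 everywhere
    E <- E + conv2_same(pixels, b$even, "replicate")^2 +
      conv2_same(pixels, b$odd, "replicate")^2
  }
  n <- colSums(maskp)
  Em <- E; Em[!maskp] <- 0
  prof <- ifelse(n > 0, colSums(Em) / pmax(n, 1), NA)
  rng <- diff(range(prof, na.rm = TRUE))
  if (is.finite(rng) && rng < 1e-12) {
    j <- (length(prof) + 1L) %/% 2L      # flat energy: fall back to the band center
  } else {
    j <- if (identical(vote_rule, "max")) which.max(prof) else which.min(prof)
  }
  vote("gabor_energy", j, cols, prof)
}

#' Mirrored-symmetry feature votes of a ROI
#'
#' Every column is a candidate midline: the right part of the ROI is
#' reflected about the candidate onto the left and compared over the
#' overlap. `mse_sym` is the mean squared intensity difference and `mgs_sym`
#' the mean absolute gradient-magnitude difference; both are minimal at the
#' true symmetry axis and vote their minimum by default (`vote_rule = "max"`
#' reproduces the maximum-error reading). Candidates with an overlap of
#' fewer than 3 columns are excluded.
#'
#' @inheritParams column_profile_features
#' @param vote_rule `"min"` (default) or `"max"` for the MSE polarity.
#' @return list of up to 2 votes (`mse_sym`, `mgs_sym`).
#' @export
mirrored_symmetry_features <- function(pixels, maskp, cols, vote_rule = "min") {
  W <- ncol(pixels)
  if (W < 5) return(list())
  G <- grad_mag(pixels)
  mse <- rep(NA_real_, W); mgs <- rep(NA_real_, W)
  for (j in seq_len(W)) {
    K <- min(j - 1L, W - j)
    if (K < 3) next
    k <- seq_len(K)
    L <- pixels[, j - k, drop = FALSE]; R <- pixels[, j + k, drop = FALSE]
    sel <- maskp[, j - k, drop = FALSE] & maskp[, j + k, drop = FALSE]
    if (!any(sel)) next
    mse[j] <- mean(((L - R)[sel])^2)
    GL <- G[, j - k, drop = FALSE]; GR <- G[, j + k, drop = FALSE]
    mgs[j] <- mean(abs((GL - GR)[sel]))
  }
  pick <- function(p, rule) {
    if (all(is.na(p))) return(NA_integer_)
    if (identical(rule, "max")) which.max(p) else which.min(p)
  }
  Filter(Negate(is.null), list(
    vote("mse_sym", pick(mse, vote_rule), cols, mse),
    vote("mgs_sym", pick(mgs, "min"), cols, mgs)))
}

#' Combine feature votes into a ROI control point
#'
#' The column is the lower median of the vote columns (robust to a stray
#' feature, deterministic for even vote counts); the row is the ROI row
#' midpoint.
#'
#' @param votes list of votes as produced by the feature functions.
#' @param row_range `c(r_first, r_last)` of the ROI.
#' @return `c(row, col)` or `NULL` when there are no votes.
#' @export
estimate_roi_control_point <- function(votes, row_range) {
  if (length(votes) == 0) return(NULL)
  cols <- vapply(votes, function(v) as.numeric(v$col), numeric(1))
  c(row = mean(row_range), col = lower_median(cols))
}

#' Estimate the control-point grid of a volume
#'
#' Runs the full ROI feature machinery over every cerebral slice (brain area
#' at least `cerebral_slice_fraction` of the largest slice). Expects the
#' volume to be head-angle corrected already.
#'
#' @param vol a [flair_volume()] in the corrected frame.
#' @param config a [default_config()] list.
#' @return object of class `control_point_grid`: matrices `col` and `row`
#'   (slices x ROIs, `NA` where absent), character matrix `flag`
#'   (`"ok"`, `"empty"`, `"repaired"`), logical `cerebral` per slice,
#'   the band column indices, and the per-ROI votes.
#' @export
estimate_control_points <- function(vol, config = default_config()) {
  d <- dim(vol$data); S <- d[1]
  dx <- vol$spacing[3]; dy <- vol$spacing[2]
  band <- extract_midline_band(d[3], dx, config$roi_mm)
  areas <- vapply(seq_len(S), function(s) sum(vol$mask[s, , ]), numeric(1))
  cerebral <- areas >= config$cerebral_slice_fraction * max(areas) & areas > 0
  n_roi_max <- ceiling(d[2] / round(config$roi_mm / dy)) + 1L
  colm <- matrix(NA_real_, S, n_roi_max)
  rowm <- matrix(NA_real_, S, n_roi_max)
  flag <- matrix("empty", S, n_roi_max)
  votes_all <- vector("list", S)
  for (s in which(cerebral)) {
    slice <- vol$data[s, , ]
    smask <- vol$mask[s, , ]
    wins <- partition_rois(smask, dy, config$roi_mm)
    votes_all[[s]] <- vector("list", length(wins))
    for (k in seq_along(wins)) {
      rr <- wins[[k]][1]:wins[[k]][2]
      px <- slice[rr, band, drop = FALSE]
      mp <- smask[rr, band, drop = FALSE]
      inv <- invert_if_csf(px, mp, config$csf_threshold)
      if (is.null(inv)) next
      if (inv$inverted) {
        # septum ROI: after inversion the septum is the dark line, but the
        # (now bright, homogeneous) ventricle interiors dominate the texture,
        # gradient and symmetry scores — only the dark-line intensity
        # profiles still measure the fissure here
        vts <- column_profile_features(inv$pixels, mp, band)
      } else {
        vts <- c(column_profile_features(inv$pixels, mp, band),
                 list(gradient_valley_feature(inv$pixels, mp, band)),
                 list(gabor_energy_feature(inv$pixels, mp, band, config$gabor_vote)),
                 mirrored_symmetry_features(inv$pixels, mp, band, config$mse_vote))
      }
      vts <- Filter(Negate(is.null), vts)
      cp <- estimate_roi_control_point(vts, wins[[k]])
      if (!is.null(cp)) {
        colm[s, k] <- cp["col"]; rowm[s, k] <- cp["row"]
        flag[s, k] <- "ok"
      }
      votes_all[[s]][[k]] <- list(votes = vts, inverted = inv$inverted,
                                  csf_fraction = inv$csf_fraction,
                                  row_range = wins[[k]])
    }
  }
  used <- which(colSums(!is.na(colm)) > 0)
  keep <- seq_len(if (length(used)) max(used) else 0L)
  structure(list(col = colm[, keep, drop = FALSE],
                 row = rowm[, keep, drop = FALSE],
                 flag = flag[, keep, drop = FALSE],
                 cerebral = cerebral, band = band, votes = votes_all,
                 spacing = vol$spacing),
            class = "control_point_grid")
}

#' Robust cross-slice repair of control points
#'
#' For each ROI index, the control-point columns across slices are screened
#' with the 3-scaled-MAD rule (scaled MAD = 1.4826 x median absolute
#' deviation; when the MAD is zero, absolute deviations above 3 px are
#' flagged instead). Flagged points are replaced by the mean of the
#' same-ROI points in the nearest unflagged neighboring slices (a single
#' neighbor at the boundary) and marked `"repaired"`. Unflagged points are
#' never moved.
#'
#' @param grid a `control_point_grid`.
#' @param mad_k flagging multiplier (default 3).
#' @return the repaired `control_point_grid`.
#' @export
refine_across_slices <- function(grid, mad_k = 3) {
  colm <- grid$col; flag <- grid$flag
  for (k in seq_len(ncol(colm))) {
    x <- colm[, k]
    present <- which(!is.na(x))
    if (length(present) < 3) next
    med <- median(x[present])
    dev <- abs(x[present] - med)
    smad <- 1.4826 * median(dev)
    bad <- if (smad > 0) dev > mad_k * smad else dev > 3
    if (!any(bad)) next
    if (all(bad)) {
      warning(sprintf("all control points flagged for ROI %d; leaving unrepaired", k))
      next
    }
    good <- present[!bad]
    for (s in present[bad]) {
      below <- good[good < s]; above <- good[good > s]
      nb <- c(if (length(below)) max(below), if (length(above)) min(above))
      colm[s, k] <- mean(x[nb])
      flag[s, k] <- "repaired"
    }
  }
  grid$col <- colm; grid$flag <- flag
  grid
}

#' @export
print.control_point_grid <- function(x, ...) {
  cat(sprintf("<control_point_grid> %d slices x %d ROIs; %d points (%d repaired), %d cerebral slices\n",
              nrow(x$col), ncol(x$col), sum(!is.na(x$col)),
              sum(x$flag == "repaired"), sum(x$cerebral)))
  invisible(x)
}

#' Control points as a tibble
#'
#' @param x a `control_point_grid`.
#' @param ... unused.
#' @return tibble with columns `slice`, `roi`, `row`, `col`, `flag`.
#' @export
tidy.control_point_grid <- function(x, ...) {
  idx <- which(!is.na(x$col), arr.ind = TRUE)
  tibble(slice = idx[, 1], roi = idx[, 2],
         row = x$row[idx], col = x$col[idx], flag = x$flag[idx])
}
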