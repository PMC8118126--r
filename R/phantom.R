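#' Specification of a synthetic FLAIR-like phantom
#'
#' Describes an elliptical "head" on the standardized intensity scale
#' (CSF < 200, NABM in \[200, 400\], lesions > 400) with a dark
#' interhemispheric fissure carved along a per-slice cubic curve, optional
#' dark lateral ventricles flanked by a bright septum pellucidum band,
#' optional lesions, per-hemisphere texture contrast and an in-plane head
#' rotation. The generator knows its own midline analytically, so estimation
#' error can be measured exactly.
#'
#' @param shape `c(slices, rows, cols)` voxel counts (min `c(5, 64, 64)`).
#' @param spacing `c(dz, dy, dx)` in mm.
#' @param theta_true in-plane head rotation in degrees, within \[-20, 20\].
#' @param fissure_poly either 4 coefficients `c(p0, p1, p2, p3)` of the
#'   fissure column as a function of the 0-based row offset, or a
#'   `slices x 4` matrix for per-slice (torqued) curves. Units: pixels.
#' @param fissure_width fissure band width in pixels.
#' @param fissure_intensity CSF intensity of the fissure (< 200).
#' @param nabm_mean,nabm_sd NABM intensity mean and texture standard
#'   deviation (clipped into \[200, 400\]).
#' @param noise_sd intensity noise s.d. for non-NABM tissue classes.
#' @param texture_contrast relative microstructural degeneration of the
#'   right hemisphere's NABM (1 = symmetric). Two effects scale with it: the
#'   white-noise weight of the unit-variance smooth/rough texture mix, and
#'   the density of small dark ridge-like damage spots shared across slices.
#'   Both are *patterns* rather than amplitudes, which is what local binary
#'   patterns respond to (LBP codes are invariant to monotone intensity
#'   changes, so a plain noise-variance multiplier would be invisible).
#' @param ventricles `NULL`, or a list with fields `slices` (slice indices),
#'   `row_halfwidth`, `col_halfwidth`, `col_offset` (pixels from the fissure),
#'   `intensity` (< 200), `septum_width` (pixels) and `septum_intensity`
#'   (inside the NABM band, bright relative to ventricular CSF).
#' @param lesions `NULL`, or a list of lists with fields `slice`, `row`,
#'   `col`, `radius` (pixels) and `intensity` (> 400).
#' @param brain_axes semi-axes of the brain ellipse as fractions of
#'   rows/cols.
#' @param brain_taper per-slice ellipse scale at the first/last slice
#'   (1 = cylinder). Keep above ~0.75 so all slices count as cerebral.
#' @param mirror if `TRUE` the left half (including noise) is reflected onto
#'   the right, producing an exactly mirror-symmetric volume; requires a
#'   fissure centered on the image.
#' @param seed integer RNG seed; generation is deterministic given the spec.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(10, 128, 128),
                         spacing = c(3, 1, 1),
                         theta_true = 0,
                         fissure_poly = c((shape[3] + 1) / 2, 0, 0, 0),
                         fissure_width = 3,
                         fissure_intensity = 120,
                         nabm_mean = 300, nabm_sd = 25,
                         noise_sd = 8,
                         texture_contrast = 1,
                         ventricles = NULL,
                         lesions = NULL,
                         brain_axes = c(0.42, 0.40),
                         brain_taper = 0.85,
                         mirror = FALSE,
                         seed = 1L) {
  if (any(shape < c(5, 64, 64))) stop("shape must be at least (5, 64, 64)")
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (abs(theta_true) > 20) stop("theta_true must lie within [-20, 20] degrees")
  if (fissure_intensity >= 200) stop("fissure_intensity must be < 200 (CSF band)")
  if (nabm_mean < 200 || nabm_mean > 400) stop("nabm_mean must lie in [200, 400]")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 theta_true = theta_true, fissure_poly = fissure_poly,
                 fissure_width = fissure_width,
                 fissure_intensity = fissure_intensity,
                 nabm_mean = nabm_mean, nabm_sd = nabm_sd, noise_sd = noise_sd,
                 texture_contrast = texture_contrast,
                 ventricles = ventricles, lesions = lesions,
                 brain_axes = brain_axes, brain_taper = brain_taper,
                 mirror = mirror, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default ventricle layout for septum-pellucidum phantoms
#'
#' Two dark CSF ellipses flanking the fissure with a bright septum band
#' between them, sized so that ventricle-bearing 2 x 2 cm ROIs are CSF
#' dominated (> 50%) and genuinely exercise the intensity-inversion test.
#'
#' @param slices slice indices carrying ventricles.
#' @return list suitable for the `ventricles` field of [phantom_spec()].
#' @export
ventricle_layout <- function(slices) {
  list(slices = slices, row_halfwidth = 13, col_halfwidth = 4.5,
       col_offset = 6.5, intensity = 110, septum_width = 2,
       septum_intensity = 350)
}

# run `expr` under a private RNG stream so phantom generation never disturbs
# (or depends on) the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic FLAIR-like phantom volume
#'
#' Builds the tissue-class geometry slice by slice, draws clipped intensities
#' per class, applies optional mirroring, and finally rotates the volume
#' in-plane by `theta_true` (bilinear for intensities, nearest for masks).
#' The analytic truth — midline samples, hemisphere masks, ventricle and
#' septum masks — is reported in the rotated (native) frame; the midline is
#' transformed as points, never resampled.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` (a [flair_volume()]) and `truth`
#'   (class `phantom_truth`: per-slice unrotated fissure polynomials `poly`,
#'   native-frame midline point samples `midline`, hemisphere masks `left`
#'   and `right`, `theta_true`, `ventricle_mask`, `septum_mask`, and the
#'   generated NABM voxel fraction `nabm_fraction`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  S <- spec$shape[1]; NR <- spec$shape[2]; NC <- spec$shape[3]
  ctr_r <- (NR + 1) / 2; ctr_c <- (NC + 1) / 2
  P <- spec$fissure_poly
  if (is.null(dim(P))) P <- matrix(rep(as.numeric(P), each = S), nrow = S)
  if (!all(dim(P) == c(S, 4))) stop("fissure_poly must be length 4 or a slices x 4 matrix")

  a_r <- spec$brain_axes[1] * NR; a_c <- spec$brain_axes[2] * NC
  sl_scale <- spec$brain_taper + (1 - spec$brain_taper) * sin(pi * (seq_len(S) - 0.5) / S)

  rows <- seq_len(NR); cols <- seq_len(NC)
  Rg <- matrix(rows, NR, NC); Cg <- matrix(cols, NR, NC, byrow = TRUE)

  # tissue class codes
  NABM <- 1L; FISS <- 2L; VENT <- 3L; SEPT <- 4L; LES <- 5L

  cls <- array(0L, c(S, NR, NC))
  vent_mask <- array(FALSE, c(S, NR, NC))
  sept_mask <- array(FALSE, c(S, NR, NC))
  right_un <- array(FALSE, c(S, NR, NC))
  midline_un <- vector("list", S)

  for (s in seq_len(S)) {
    ar <- a_r * sl_scale[s]; ac <- a_c * sl_scale[s]
    inside <- ((Rg - ctr_r) / ar)^2 + ((Cg - ctr_c) / ac)^2 <= 1
    ct <- polyval0(P[s, ], rows - 1)          # fissure column per row (1-based col)
    brain_rows <- which(apply(inside, 1, any))
    # fissure must stay inside the brain wherever the brain is wide enough to
    # carry it (the 1-2 px polar caps of the ellipse carry no fissure)
    hw <- ac * sqrt(pmax(0, 1 - ((brain_rows - ctr_r) / ar)^2))
    chk <- hw >= spec$fissure_width
    if (any(abs(ct[brain_rows[chk]] - ctr_c) >= hw[chk])) {
      stop(sprintf("fissure leaves the brain ellipse on slice %d", s))
    }
    c_mat <- matrix(ct, NR, NC)
    csl <- matrix(0L, NR, NC)
    csl[inside] <- NABM
    fband <- inside & abs(Cg - c_mat) <= spec$fissure_width / 2
    csl[fband] <- FISS
    vsl <- matrix(FALSE, NR, NC); ssl <- matrix(FALSE, NR, NC)
    vs <- spec$ventricles
    if (!is.null(vs) && s %in% vs$slices) {
      for (sgn in c(-1, 1)) {
        vc <- c_mat + sgn * vs$col_offset
        ell <- ((Rg - ctr_r) / vs$row_halfwidth)^2 + ((Cg - vc) / vs$col_halfwidth)^2 <= 1
        vsl <- vsl | (ell & inside)
      }
      vrows <- abs(Rg - ctr_r) <= vs$row_halfwidth
      ssl <- inside & vrows & abs(Cg - c_mat) <= vs$septum_width / 2 & !vsl
      csl[vsl] <- VENT
      csl[ssl] <- SEPT
    }
    cls[s, , ] <- csl
    vent_mask[s, , ] <- vsl
    sept_mask[s, , ] <- ssl
    right_un[s, , ] <- Cg >= c_mat            # half-open rule, unrotated frame
    midline_un[[s]] <- cbind(row = brain_rows, col = ct[brain_rows])
  }

  for (le in spec$lesions) {
    ar2 <- le$radius; s0 <- le$slice
    blob <- ((Rg - le$row) / ar2)^2 + ((Cg - le$col) / ar2)^2 <= 1
    csl <- cls[s0, , ]
    csl[blob & csl != 0L] <- LES
    cls[s0, , ] <- csl
  }

  vol_un <- with_seed(spec$seed, {
    white <- array(rnorm(S * NR * NC), c(S, NR, NC))
    # spatially smoothed unit-variance companion field (3x3 moving average)
    smooth <- array(0, c(S, NR, NC))
    k33 <- matrix(1 / 9, 3, 3)
    raw <- array(rnorm(S * NR * NC), c(S, NR, NC))
    for (s in seq_len(S)) smooth[s, , ] <- conv2_same(raw[s, , ], k33) * 3
    # NABM texture: mix of smooth and white noise; texture_contrast scales the
    # white (rough) weight of the right hemisphere
    w_l <- 0.4
    w_r <- min(1, w_l * spec$texture_contrast)
    mix <- function(w) sqrt(pmax(0, 1 - w^2)) * smooth + w * white
    eps_nabm <- mix(w_l)
    if (w_r != w_l) eps_nabm[right_un] <- mix(w_r)[right_un]
    # volume-persistent microstructural damage of the right hemisphere: small
    # dark ridges whose density grows with texture_contrast. Persistence
    # across slices matters — the pixel-wise slice average only retains
    # structure aligned through the volume.
    if (spec$texture_contrast > 1) {
      rate <- 0.005 * (spec$texture_contrast - 1)
      nsp <- max(1L, round(rate * NR * NC))
      rs <- sample(3:(NR - 3), nsp, replace = TRUE)
      csp <- sample(3:(NC - 3), nsp, replace = TRUE)
      bump <- outer(-2:2, -2:2, function(a, b) exp(-(a^2 + b^2) / 2))
      D <- matrix(0, NR, NC)
      for (k in seq_len(nsp)) {
        D[(rs[k] - 2):(rs[k] + 2), (csp[k] - 2):(csp[k] + 2)] <-
          D[(rs[k] - 2):(rs[k] + 2), (csp[k] - 2):(csp[k] + 2)] - 3 * bump
      }
      sel_r <- right_un
      for (s in seq_len(S)) {
        eps_s <- eps_nabm[s, , ]
        eps_s[sel_r[s, , ]] <- eps_s[sel_r[s, , ]] + D[sel_r[s, , ]]
        eps_nabm[s, , ] <- eps_s
      }
    }
    v <- array(0, c(S, NR, NC))
    base <- c(spec$nabm_mean, spec$fissure_intensity,
              if (is.null(spec$ventricles)) 110 else spec$ventricles$intensity,
              if (is.null(spec$ventricles)) 350 else spec$ventricles$septum_intensity,
              450)
    sel <- cls == NABM
    v[sel] <- base[NABM] + spec$nabm_sd * eps_nabm[sel]
    for (k in 2:5) {
      sel <- cls == k
      if (any(sel)) v[sel] <- base[k] + spec$noise_sd * white[sel]
    }
    # clip each class into its standardized band
    v[cls == NABM] <- clip(v[cls == NABM], 200, 400)
    v[cls == FISS] <- clip(v[cls == FISS], 20, 195)
    v[cls == VENT] <- clip(v[cls == VENT], 20, 195)
    v[cls == SEPT] <- clip(v[cls == SEPT], 205, 395)
    v[cls == LES]  <- clip(v[cls == LES], 405, 600)
    v
  })
  mask_un <- cls != 0L

  if (spec$mirror) {
    # reflect the left half (cols 1..floor(NC/2)) onto the right
    src <- seq_len(NC %/% 2)
    dst <- NC + 1L - src
    vol_un[, , dst] <- vol_un[, , src]
    mask_un[, , dst] <- mask_un[, , src]
    cls[, , dst] <- cls[, , src]
    vent_mask[, , dst] <- vent_mask[, , src]
    sept_mask[, , dst] <- sept_mask[, , src]
  }

  th <- spec$theta_true
  if (th != 0) {
    data <- array(0, c(S, NR, NC)); mask <- array(FALSE, c(S, NR, NC))
    vmr <- array(FALSE, c(S, NR, NC)); smr <- array(FALSE, c(S, NR, NC))
    for (s in seq_len(S)) {
      data[s, , ] <- rotate_matrix(vol_un[s, , ], th, "bilinear")
      mask[s, , ] <- rotate_matrix(mask_un[s, , ], th, "nearest")
      vmr[s, , ] <- rotate_matrix(vent_mask[s, , ], th, "nearest")
      smr[s, , ] <- rotate_matrix(sept_mask[s, , ], th, "nearest")
    }
    vent_mask <- vmr; sept_mask <- smr
    midline <- lapply(midline_un, rotate_points, theta = th, dim = c(NR, NC))
  } else {
    data <- vol_un; mask <- mask_un
    midline <- midline_un
  }

  # hemisphere truth on the *native* mask, assigned analytically: map each
  # native voxel back to the unrotated frame and apply the half-open rule
  left <- array(FALSE, c(S, NR, NC)); right <- array(FALSE, c(S, NR, NC))
  for (s in seq_len(S)) {
    idx <- which(mask[s, , ], arr.ind = TRUE)
    if (nrow(idx) == 0) next
    src <- rotate_points(idx, -th, c(NR, NC))
    ct_at <- polyval0(P[s, ], src[, 1] - 1)
    is_right <- src[, 2] >= ct_at
    rsl <- matrix(FALSE, NR, NC); lsl <- matrix(FALSE, NR, NC)
    rsl[idx[is_right, , drop = FALSE]] <- TRUE
    lsl[idx[!is_right, , drop = FALSE]] <- TRUE
    left[s, , ] <- lsl; right[s, , ] <- rsl
  }

  vol <- flair_volume(data, spacing = spec$spacing, mask = mask,
                      meta = list(source = "phantom", seed = spec$seed))
  truth <- structure(list(poly = P, midline = midline, left = left,
                          right = right, theta_true = th,
                          ventricle_mask = vent_mask, septum_mask = sept_mask,
                          nabm_fraction = sum(cls == NABM) / max(1L, sum(cls != 0L))),
                     class = "phantom_truth")
  list(volume = vol, truth = truth)
}

#' Standard phantom validation suite
#'
#' The mix of geometries used to validate the midline pipeline: straight
#' fissures, curved cubic fissures (occipital deflection of ~3 px at 1 mm
#' in-plane, the scale of natural brain torque), per-slice-varying (torqued)
#' cubics, 10-degree rotated heads, and septum-pellucidum phantoms with
#' ventricles. Specs cycle through the five conditions.
#'
#' @param n number of specs.
#' @param seed base seed; spec `i` uses `seed + i`.
#' @return list of `n` [phantom_spec()] objects with a `condition` attribute.
#' @export
phantom_suite <- function(n = 20, seed = 1L) {
  base <- phantom_spec()
  C <- base$fissure_poly[1]
  S <- base$shape[1]
  conds <- c("straight", "curved", "torque", "rotated", "septum")
  lapply(seq_len(n), function(i) {
    cond <- conds[(i - 1L) %% length(conds) + 1L]
    sp <- switch(cond,
      straight = phantom_spec(seed = seed + i),
      curved = phantom_spec(fissure_poly = c(C - 2, 0.08, -1.2e-3, 4e-6),
                            seed = seed + i),
      torque = phantom_spec(fissure_poly = cbind(C + seq(-1, 1, length.out = S),
                                                 0.03, -6e-4,
                                                 seq(1e-6, 4e-6, length.out = S)),
                            seed = seed + i),
      rotated = phantom_spec(theta_true = 10, seed = seed + i),
      septum = phantom_spec(ventricles = ventricle_layout(4:7), seed = seed + i))
    attr(sp, "condition") <- cond
    sp
  })
}

#' Generate a cohort of phantoms with optional corrupted volumes
#'
#' Draws `n` phantoms around `base_spec`, jittering selected parameters
#' uniformly within the supplied ranges. A fraction of the cohort (rounded to
#' the nearest count) is corrupted by truncating the outer part of one
#' hemisphere — the dominant real-world failure mode (off-center brains,
#' missing tissue in the brain mask) that the asymmetry-index QC must catch.
#'
#' @param n cohort size (>= 2).
#' @param base_spec a [phantom_spec()] used as template.
#' @param jitter named list of `c(lo, hi)` ranges applied additively to
#'   `theta` (degrees), `p0` (pixels) and `p3` (cubic coefficient); any subset.
#' @param corrupt_fraction proportion in \[0, 1\] of corrupted volumes.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return list of `n` elements, each `list(volume, truth, is_corrupt)`.
#' @export
generate_cohort <- function(n, base_spec = phantom_spec(),
                            jitter = list(theta = c(-5, 5), p0 = c(-3, 3)),
                            corrupt_fraction = 0, seed = 1L) {
  if (n < 2) stop("n must be >= 2")
  if (corrupt_fraction < 0 || corrupt_fraction > 1) {
    stop("corrupt_fraction must lie in [0, 1]")
  }
  n_corrupt <- round(n * corrupt_fraction)
  plan <- with_seed(seed, {
    list(corrupt = if (n_corrupt > 0) sample(n, n_corrupt) else integer(0),
         theta = if (!is.null(jitter$theta)) runif(n, jitter$theta[1], jitter$theta[2]) else numeric(n),
         p0 = if (!is.null(jitter$p0)) runif(n, jitter$p0[1], jitter$p0[2]) else numeric(n),
         p3 = if (!is.null(jitter$p3)) runif(n, jitter$p3[1], jitter$p3[2]) else numeric(n),
         side = sample(c(-1, 1), n, replace = TRUE),
         sub_seed = sample.int(2^20, n))
  })
  lapply(seq_len(n), function(i) {
    sp <- base_spec
    sp$theta_true <- clip(sp$theta_true + plan$theta[i], -20, 20)
    fp <- sp$fissure_poly
    if (is.null(dim(fp))) {
      fp[1] <- fp[1] + plan$p0[i]; fp[4] <- fp[4] + plan$p3[i]
    } else {
      fp[, 1] <- fp[, 1] + plan$p0[i]; fp[, 4] <- fp[, 4] + plan$p3[i]
    }
    sp$fissure_poly <- fp
    sp$seed <- plan$sub_seed[i]
    ph <- generate_phantom(sp)
    is_corrupt <- i %in% plan$corrupt
    if (is_corrupt) ph <- truncate_hemisphere(ph, side = plan$side[i])
    list(volume = ph$volume, truth = ph$truth, is_corrupt = is_corrupt)
  })
}

# corrupt a phantom by removing the outer part of one hemisphere (well above
# the 20%-of-one-side floor), emulating the gross failure modes the QC must
# catch: brain-extraction errors and badly off-center acquisitions
truncate_hemisphere <- function(ph, side = 1) {
  NC <- dim(ph$volume$data)[3]
  ctr_c <- (NC + 1) / 2
  half_extent <- 0.40 * NC        # matches default brain_axes col semi-axis
  cut <- ctr_c + side * 0.25 * half_extent
  sel <- if (side > 0) seq_len(NC) > cut else seq_len(NC) < cut
  ph$volume$data[, , sel] <- 0
  ph$volume$mask[, , sel] <- FALSE
  ph$truth$left[, , sel] <- FALSE
  ph$truth$right[, , sel] <- FALSE
  ph
}

#' Write a phantom and its truth to disk
#'
#' Serializes the volume and brain mask as NIfTI, the truth midline as a
#' per-slice CSV of (slice, row, col) samples, and the per-slice fissure
#' polynomial coefficients plus rotation as JSON.
#'
#' @param ph result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @param stem file stem for the outputs.
#' @return invisibly, the named vector of written paths.
#' @export
write_phantom <- function(ph, dir, stem = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(volume = file.path(dir, paste0(stem, ".nii.gz")),
             mask = file.path(dir, paste0(stem, "_mask.nii.gz")),
             midline_csv = file.path(dir, paste0(stem, "_midline.csv")),
             truth_json = file.path(dir, paste0(stem, "_truth.json")))
  write_volume(ph$volume, paths[["volume"]], paths[["mask"]])
  ml <- do.call(rbind, lapply(seq_along(ph$truth$midline), function(s) {
    m <- ph$truth$midline[[s]]
    data.frame(slice = s, row = m[, 1], col = m[, 2])
  }))
  write.csv(ml, paths[["midline_csv"]], row.names = FALSE)
  jsonlite::write_json(list(theta_true = ph$truth$theta_true,
                            fissure_poly = ph$truth$poly),
                       paths[["truth_json"]], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
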