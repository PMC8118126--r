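# Hemispheric texture asymmetry biomarkers of the normal-appearing brain
# matter (NABM): per-slice local binary pattern (LBP) maps, pixel-wise slice
# averaging, 5 first-order + 5 co-occurrence texture features per hemisphere,
# normalized asymmetries, and Box-Cox / ANOVA / Tukey HSD / ANCOVA group
# statistics.

# binary erosion by a (2r+1) x (2r+1) square window
erode_mask <- function(mask, r) {
  k <- matrix(1, 2 * r + 1, 2 * r + 1)
  conv2_same(mask * 1, k) > length(k) - 0.5
}

#' NABM mask of a standardized volume
#'
#' Brain-mask voxels with intensities inside the NABM band (default
#' \[200, 400\], inclusive), which removes CSF and hyperintense lesions.
#'
#' @param vol a [flair_volume()].
#' @param band `c(low, high)` standardized intensities.
#' @return logical 3D array.
#' @export
nabm_mask <- function(vol, band = c(200, 400)) {
  m <- vol$mask & vol$data >= band[1] & vol$data <= band[2]
  if (!any(m)) warning("NABM mask is empty")
  m
}

#' Local binary pattern map of a slice
#'
#' Classical 8-bit LBP: each of 8 neighbors sampled on a circle of the given
#' radius (bilinear interpolation for off-grid positions) contributes bit 1
#' when its intensity is `>=` the center (ties count as 1, so a constant
#' patch codes 255). Codes are produced only where the full
#' `(2r+1) x (2r+1)` neighborhood lies inside the image, and restricted to
#' `mask` pixels.
#'
#' @param slice numeric matrix (row, col).
#' @param mask logical matrix; `NULL` for all pixels.
#' @param radius circle radius in px (default 3, i.e. a 7 x 7 window).
#' @param neighbors number of circle samples (default 8).
#' @return numeric matrix of codes in \[0, 255\], `NA` outside the valid
#'   region or mask.
#' @export
lbp_map <- function(slice, mask = NULL, radius = 3, neighbors = 8) {
  nr <- nrow(slice); nc <- ncol(slice)
  if (nr <= 2 * radius || nc <= 2 * radius) stop("slice smaller than the LBP window")
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  rows <- (radius + 1):(nr - radius)
  cols <- (radius + 1):(nc - radius)
  center <- slice[rows, cols, drop = FALSE]
  code <- matrix(0, length(rows), length(cols))
  for (k in 0:(neighbors - 1)) {
    a <- 2 * pi * k / neighbors
    dr <- -radius * sin(a); dc <- radius * cos(a)
    # snap near-integer offsets so axis-aligned neighbors are exact
    if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)
    if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
    r0 <- floor(dr); c0 <- floor(dc)
    fr <- dr - r0; fc <- dc - c0
    sub <- function(or_, oc_) slice[rows + or_, cols + oc_, drop = FALSE]
    nb <- sub(r0, c0) * (1 - fr) * (1 - fc)
    if (fr > 0) nb <- nb + sub(r0 + 1, c0) * fr * (1 - fc)
    if (fc > 0) nb <- nb + sub(r0, c0 + 1) * (1 - fr) * fc
    if (fr > 0 && fc > 0) nb <- nb + sub(r0 + 1, c0 + 1) * fr * fc
    code <- code + (nb >= center) * 2^k
  }
  out <- matrix(NA_real_, nr, nc)
  out[rows, cols] <- code
  out[!mask] <- NA_real_
  out
}

#' Pixel-wise average of per-slice code maps
#'
#' Averages LBP codes across slices at each pixel, using only the slices
#' where the pixel carries a code (is inside the NABM mask), yielding a
#' single texture image per hemisphere.
#'
#' @param maps list of per-slice code matrices (`NA` = no code).
#' @return object of class `texture_image`: `avg` (mean code, `NA` without
#'   support), `support` (logical, >= 1 contributing slice), `coverage`
#'   (contributing slice count).
#' @export
pixelwise_average <- function(maps) {
  if (length(maps) == 0) stop("need at least one slice map")
  acc <- matrix(0, nrow(maps[[1]]), ncol(maps[[1]]))
  cov <- matrix(0L, nrow(maps[[1]]), ncol(maps[[1]]))
  for (m in maps) {
    ok <- !is.na(m)
    acc[ok] <- acc[ok] + m[ok]
    cov <- cov + ok
  }
  avg <- matrix(NA_real_, nrow(acc), ncol(acc))
  sup <- cov > 0
  avg[sup] <- acc[sup] / cov[sup]
  structure(list(avg = avg, support = sup, coverage = cov),
            class = "texture_image")
}

# gray-level co-occurrence matrix of a (possibly NA-holed) image, quantized
# to `levels`, offset 1 px over 4 orientations, symmetrized and normalized
glcm_matrix <- function(avg, support, levels = 32) {
  vals <- avg[support]
  mn <- min(vals); mx <- max(vals)
  q <- matrix(NA_integer_, nrow(avg), ncol(avg))
  if (mx > mn) {
    q[support] <- pmin(levels, floor((avg[support] - mn) / (mx - mn) * levels) + 1L)
  } else {
    q[support] <- 1L
  }
  counts <- matrix(0, levels, levels)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  nr <- nrow(q); nc <- ncol(q)
  for (o in offs) {
    r1 <- max(1, 1 - o[1]):min(nr, nr - o[1])
    c1 <- max(1, 1 - o[2]):min(nc, nc - o[2])
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + o[1], c1 + o[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    idx <- (a[ok] - 1L) * levels + b[ok]
    tab <- tabulate(idx, nbins = levels * levels)
    counts <- counts + matrix(tab, levels, levels, byrow = TRUE)
  }
  counts <- counts + t(counts)     # symmetrize
  tot <- sum(counts)
  if (tot == 0) return(NULL)
  counts / tot
}

#' Texture features of a slice-averaged code image
#'
#' Five first-order statistics of the averaged codes over the support (mean,
#' median, variance, skewness and kurtosis as standardized 3rd/4th moments,
#' kurtosis non-excess) plus five second-order features: contrast, energy
#' (angular second moment), correlation and homogeneity from a 32-level,
#' offset-1, 4-orientation symmetric gray-level co-occurrence matrix, and
#' Shannon entropy (base 2) of the 32-bin histogram. A constant map yields
#' variance 0 with skewness/kurtosis/correlation reported as 0 (warning).
#'
#' @param img a `texture_image` from [pixelwise_average()].
#' @param levels number of quantization levels (default 32).
#' @return named numeric of length 10: `mean`, `median`, `variance`,
#'   `skewness`, `kurtosis`, `contrast`, `energy`, `correlation`,
#'   `homogeneity`, `entropy`.
#' @export
texture_features <- function(img, levels = 32) {
  vals <- img$avg[img$support]
  n <- length(vals)
  if (n == 0) stop("texture image has empty support")
  if (n < 100) warning("texture support below 100 px; features may be unstable")
  mu <- mean(vals)
  m2 <- mean((vals - mu)^2)
  if (m2 == 0) {
    warning("constant texture map: skewness and kurtosis undefined, reported as 0")
    skew <- 0; kurt <- 0
  } else {
    skew <- mean((vals - mu)^3) / m2^1.5
    kurt <- mean((vals - mu)^4) / m2^2
  }
  P <- glcm_matrix(img$avg, img$support, levels)
  if (is.null(P)) {
    contrast <- 0; energy <- 1; correlation <- 0; homogeneity <- 1
  } else {
    i <- matrix(seq_len(levels), levels, levels)
    j <- t(i)
    contrast <- sum(P * (i - j)^2)
    energy <- sum(P^2)
    mui <- sum(i * P); muj <- sum(j * P)
    sdi <- sqrt(sum((i - mui)^2 * P)); sdj <- sqrt(sum((j - muj)^2 * P))
    if (sdi == 0 || sdj == 0) {
      warning("degenerate co-occurrence matrix: correlation reported as 0")
      correlation <- 0
    } else {
      correlation <- sum((i - mui) * (j - muj) * P) / (sdi * sdj)
    }
    homogeneity <- sum(P / (1 + abs(i - j)))
  }
  # first-order histogram entropy on the same quantization
  mn <- min(vals); mx <- max(vals)
  lev <- if (mx > mn) pmin(levels, floor((vals - mn) / (mx - mn) * levels) + 1L) else rep(1L, n)
  p <- tabulate(lev, nbins = levels) / n
  p <- p[p > 0]
  entropy <- -sum(p * log2(p))
  c(mean = mu, median = median(vals), variance = stats::var(vals) * (n - 1) / n,
    skewness = skew, kurtosis = kurt,
    contrast = contrast, energy = energy, correlation = correlation,
    homogeneity = homogeneity, entropy = entropy)
}

#' Normalized hemispheric feature asymmetry
#'
#' `delta_f = |f_L - f_R| / (f_L + f_R)` per feature; a zero denominator
#' yields 0 with a warning.
#'
#' @param f_left,f_right named feature vectors (see [texture_features()]).
#' @return named vector of asymmetries.
#' @export
asymmetry_features <- function(f_left, f_right) {
  denom <- f_left + f_right
  delta <- abs(f_left - f_right) / denom
  zero <- denom == 0
  if (any(zero)) {
    warning("zero feature denominator for: ",
            paste(names(f_left)[zero], collapse = ", "))
    delta[zero] <- 0
  }
  delta
}

#' Hemispheric texture biomarkers of one subject
#'
#' Resamples the volume to the common biomarker grid, extracts the NABM of
#' each hemisphere, computes per-slice LBP maps, averages them pixel-wise
#' across slices, and returns the 10 features per hemisphere plus the
#' normalized asymmetries.
#'
#' @param vol a standardized [flair_volume()].
#' @param hemis a `hemisphere_pair` on the same grid.
#' @param config a [default_config()] list.
#' @param resample resample to `config$biomarker_spacing` first (default
#'   TRUE; disable when the volume is already on the target grid).
#' @return one-row tibble with `f_left_*`, `f_right_*` and `delta_*` columns.
#' @export
hemispheric_biomarkers <- function(vol, hemis, config = default_config(),
                                   resample = TRUE) {
  if (resample) {
    hv_l <- flair_volume(vol$data, vol$spacing, mask = vol$mask & hemis$left)
    hv_r <- flair_volume(vol$data, vol$spacing, mask = vol$mask & hemis$right)
    hv_l <- resample_volume(hv_l, config$biomarker_spacing)
    hv_r <- resample_volume(hv_r, config$biomarker_spacing)
  } else {
    hv_l <- flair_volume(vol$data, vol$spacing, mask = vol$mask & hemis$left)
    hv_r <- flair_volume(vol$data, vol$spacing, mask = vol$mask & hemis$right)
  }
  feat <- function(hv, flip) {
    nm <- nabm_mask(hv, config$nabm_band)
    S <- dim(hv$data)[1]
    maps <- lapply(seq_len(S), function(s) {
      sl <- hv$data[s, , ]
      # erode by the LBP radius: codes whose window touches non-NABM tissue
      # encode the fissure/ventricle walls, not microstructure
      msk <- erode_mask(nm[s, , ], config$lbp_radius)
      # the right hemisphere is analyzed in mirrored orientation so both
      # hemispheres share an anatomical frame: LBP codes are directional, and
      # without the flip identical mirrored tissue would code differently
      if (flip) {
        sl <- sl[, rev(seq_len(ncol(sl))), drop = FALSE]
        msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
      }
      lbp_map(sl, msk,
              radius = config$lbp_radius, neighbors = config$lbp_neighbors)
    })
    texture_features(pixelwise_average(maps), config$glcm_levels)
  }
  fl <- feat(hv_l, flip = FALSE); fr <- feat(hv_r, flip = TRUE)
  delta <- asymmetry_features(fl, fr)
  out <- c(setNames(fl, paste0("f_left_", names(fl))),
           setNames(fr, paste0("f_right_", names(fr))),
           setNames(delta, paste0("delta_", names(delta))))
  as_tibble(as.list(out))
}

# Box-Cox transform with maximum-likelihood lambda; zeros are shifted by half
# the smallest positive value first (the features are nonnegative)
boxcox_transform <- function(y, lambda_grid = seq(-2, 2, by = 0.05)) {
  shift <- 0
  if (any(y <= 0)) {
    pos <- y[y > 0]
    if (length(pos) == 0) stop("Box-Cox requires some positive values")
    shift <- 0.5 * min(pos) - min(y[y <= 0])
  }
  ys <- y + shift
  bc <- MASS::boxcox(ys ~ 1, data = data.frame(ys = ys),
                     lambda = lambda_grid, plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  z <- if (abs(lambda) < 1e-8) log(ys) else (ys^lambda - 1) / lambda
  list(y = z, lambda = lambda, shift = shift)
}

#' Group comparison of an asymmetry biomarker
#'
#' Box-Cox transforms the feature (maximum-likelihood lambda), then runs a
#' one-way ANOVA across diagnosis groups with Tukey HSD post-hoc pairwise
#' comparisons; with a covariate (`age` or `sex`) an ANCOVA linear model is
#' fitted instead, group and covariate tested by Type-II F-tests, and
#' pairwise comparisons performed on covariate-adjusted means (Tukey
#' adjustment via `emmeans`).
#'
#' @param data data frame with the feature column, a `group` column and any
#'   covariate columns.
#' @param feature name of the feature column.
#' @param group name of the grouping column (default `"diagnosis"`).
#' @param covariate `"none"`, or the name of a covariate column.
#' @param boxcox apply the Box-Cox transform first (default TRUE).
#' @return object of class `fissura_grouptest` with `anova` (term-level F
#'   tests) and `pairwise` (Tukey-adjusted contrasts) tibbles.
#' @export
group_tests <- function(data, feature, group = "diagnosis",
                        covariate = "none", boxcox = TRUE) {
  df <- as.data.frame(data)
  for (nm in c(feature, group)) {
    if (!nm %in% names(df)) stop("column not found: ", nm)
  }
  df$.g <- factor(df[[group]])
  df$.y <- df[[feature]]
  if (nlevels(df$.g) < 2) stop("need at least 2 groups")
  sizes <- table(df$.g)
  if (any(sizes < 3)) stop("each group needs at least 3 subjects")
  vv <- tapply(df$.y, df$.g, var)
  if (any(vv == 0)) {
    stop("zero within-group variance in group: ",
         paste(names(vv)[vv == 0], collapse = ", "))
  }
  lambda <- NA_real_
  if (boxcox) {
    bt <- boxcox_transform(df$.y)
    df$.y <- bt$y; lambda <- bt$lambda
  }
  if (identical(covariate, "none")) {
    fit <- aov(.y ~ .g, data = df)
    sm <- summary(fit)[[1]]
    anova_tbl <- tibble(term = c(group, "Residuals"),
                        df = sm[["Df"]],
                        statistic = sm[["F value"]],
                        p.value = sm[["Pr(>F)"]])
    tk <- TukeyHSD(fit)$`.g`
    pairwise_tbl <- tibble(contrast = rownames(tk),
                           estimate = tk[, "diff"],
                           adj.p.value = tk[, "p adj"])
  } else {
    if (!covariate %in% names(df)) stop("column not found: ", covariate)
    df$.x <- df[[covariate]]
    if (is.character(df$.x)) df$.x <- factor(df$.x)
    fit <- lm(.y ~ .x + .g, data = df)
    an <- car::Anova(fit, type = 2)
    anova_tbl <- tibble(term = c(group, covariate, "Residuals"),
                        df = an[c(".g", ".x", "Residuals"), "Df"],
                        statistic = an[c(".g", ".x", "Residuals"), "F value"],
                        p.value = an[c(".g", ".x", "Residuals"), "Pr(>F)"])
    em <- emmeans::emmeans(fit, ".g")
    pr <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
    pairwise_tbl <- tibble(contrast = gsub(" - ", "-", pr$contrast),
                           estimate = pr$estimate,
                           adj.p.value = pr$p.value)
  }
  structure(list(feature = feature, group = group, covariate = covariate,
                 lambda = lambda, anova = anova_tbl, pairwise = pairwise_tbl,
                 n = nrow(df), groups = levels(df$.g)),
            class = "fissura_grouptest")
}

#' @export
print.fissura_grouptest <- function(x, ...) {
  g <- x$anova[x$anova$term == x$group, ]
  cat(sprintf("<fissura_grouptest> %s ~ %s%s (n = %d)\n", x$feature, x$group,
              if (identical(x$covariate, "none")) "" else paste0(" + ", x$covariate),
              x$n))
  cat(sprintf("  group F = %.3f, p = %.4g; Box-Cox lambda = %s\n",
              g$statistic, g$p.value,
              if (is.na(x$lambda)) "none" else sprintf("%.2f", x$lambda)))
  invisible(x)
}

#' Tidy a group-test result
#'
#' @param x a `fissura_grouptest`.
#' @param ... unused.
#' @return tibble of Tukey-adjusted pairwise contrasts.
#' @export
tidy.fissura_grouptest <- function(x, ...) x$pairwise

#' One-row summary of a group-test result
#'
#' @param x a `fissura_grouptest`.
#' @param ... unused.
#' @return one-row tibble with the group F statistic, p-value, covariate
#'   statistics when present, and the Box-Cox lambda.
#' @export
glance.fissura_grouptest <- function(x, ...) {
  g <- x$anova[x$anova$term == x$group, ]
  cv <- x$anova[x$anova$term == x$covariate, ]
  tibble(feature = x$feature, covariate = x$covariate,
         statistic = g$statistic, p.value = g$p.value,
         covariate_statistic = if (nrow(cv)) cv$statistic else NA_real_,
         covariate_p.value = if (nrow(cv)) cv$p.value else NA_real_,
         lambda = x$lambda, n = x$n)
}
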