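test_that("the 2 cm midline band is centered on the middle column", {
  expect_equal(extract_midline_band(200, 1), 91:110)
  expect_length(extract_midline_band(256, 0.5), 40)
  expect_error(extract_midline_band(15, 1), "narrower")
})

test_that("ROI windows tile the brain rows with the half-window rule", {
  mk <- function(rows, nr = 200) {
    m <- matrix(FALSE, nr, 30); m[rows, ] <- TRUE; m
  }
  w <- partition_rois(mk(10:169), dy = 1)
  expect_length(w, 8)
  expect_true(all(vapply(w, function(x) diff(x) + 1, numeric(1)) == 20))
  expect_equal(w[[1]], c(10, 29))

  w2 <- partition_rois(mk(10:44), dy = 1)
  expect_equal(w2, list(c(10, 29), c(30, 44)))   # partial 15 >= 10 kept

  w3 <- partition_rois(mk(10:38), dy = 1)
  expect_equal(w3, list(c(10, 38)))              # partial 9 < 10 merged

  expect_equal(partition_rois(matrix(FALSE, 50, 30), dy = 1), list())
})

test_that("CSF-dominated ROIs are inverted, others untouched", {
  px <- matrix(300, 20, 20); mp <- matrix(TRUE, 20, 20)
  px[, 1:12] <- 100                              # 60% CSF
  inv <- fissura:::invert_if_csf(px, mp, 200)
  expect_true(inv$inverted)
  expect_equal(inv$pixels[1, 1], 300 - 100)      # max - pixel
  px2 <- matrix(300, 20, 20); px2[, 1:8] <- 100  # 40%
  inv2 <- fissura:::invert_if_csf(px2, mp, 200)
  expect_false(inv2$inverted)
  expect_identical(inv2$pixels, px2)
  expect_null(fissura:::invert_if_csf(px, matrix(FALSE, 20, 20), 200))
})

test_that("septum ROIs invert and vote the septum column", {
  ph <- generate_phantom(septum_spec(seed = 11))
  vol <- ph$volume
  band <- extract_midline_band(dim(vol$data)[3], 1)
  s <- 5                                          # ventricle-bearing slice
  rows <- 55:74                                   # ROI over the ventricle body
  px <- vol$data[s, rows, band]
  mp <- vol$mask[s, rows, band]
  inv <- fissura:::invert_if_csf(px, mp, 200)
  expect_true(inv$inverted)
  vts <- column_profile_features(inv$pixels, mp, band)
  cp <- estimate_roi_control_point(vts, c(55, 74))
  expect_lte(abs(cp["col"] - 64.5), 2)
})

test_that("intensity profile features vote the dark column", {
  px <- matrix(300, 20, 21); mp <- matrix(TRUE, 20, 21)
  px[, 8] <- 100
  cols <- 41:61
  v <- column_profile_features(px, mp, cols)
  nm <- vapply(v, `[[`, character(1), "feature")
  for (f in c("int_sum", "int_energy", "int_rms")) {
    expect_equal(v[[which(nm == f)]]$col, cols[8])
  }
})

test_that("cumulative energy votes the center of a mirror-symmetric ROI", {
  set.seed(1)
  half <- matrix(rnorm(20 * 10, 300, 30), 20, 10)
  px <- cbind(half, matrix(250, 20, 1), half[, 10:1])
  mp <- matrix(TRUE, 20, 21)
  v <- column_profile_features(px, mp, 1:21)
  nm <- vapply(v, `[[`, character(1), "feature")
  expect_equal(v[[which(nm == "cum_energy")]]$col, 11)
})

test_that("profile features match an independent per-column loop", {
  set.seed(2)
  px <- matrix(runif(20 * 15, 100, 400), 20, 15)
  mp <- matrix(runif(20 * 15) > 0.2, 20, 15)
  mp[, 4] <- TRUE                                # ensure no empty columns issues
  v <- column_profile_features(px, mp, 1:15)
  prof_sum <- prof_en <- prof_rms <- rep(NA_real_, 15)
  for (j in 1:15) {
    vals <- px[mp[, j], j]
    if (length(vals)) {
      prof_sum[j] <- sum(vals); prof_en[j] <- sum(vals^2)
      prof_rms[j] <- sqrt(mean(vals^2))
    }
  }
  nm <- vapply(v, `[[`, character(1), "feature")
  expect_equal(v[[which(nm == "int_sum")]]$col, which.min(prof_sum))
  expect_equal(v[[which(nm == "int_energy")]]$col, which.min(prof_en))
  expect_equal(v[[which(nm == "int_rms")]]$col, which.min(prof_rms))
  expect_equal(v[[which(nm == "int_rms")]]$profile, prof_rms)
})

test_that("gradient valley votes between the fissure wall peaks", {
  px <- matrix(300, 20, 15)
  px[, 7:9] <- 100                               # dark band, walls at 6/7 and 9/10
  mp <- matrix(TRUE, 20, 15)
  v <- gradient_valley_feature(px, mp, 1:15)
  expect_equal(v$col, 8)

  flat <- gradient_valley_feature(matrix(300, 20, 15), mp, 1:15)
  expect_equal(flat$col, 1)                      # no peaks: global argmin, leftmost

  ph <- generate_phantom(small_spec(seed = 3))
  band <- extract_midline_band(96, 1)
  px2 <- ph$volume$data[3, 31:50, band]
  mp2 <- ph$volume$mask[3, 31:50, band]
  v2 <- gradient_valley_feature(px2, mp2, band)
  expect_lte(abs(v2$col - 48.5), 2.5)
})

test_that("Gabor energy is low in a homogeneous stripe and flat maps vote center", {
  set.seed(4)
  px <- matrix(rnorm(24 * 24, 300, 40), 24, 24)
  px[, 10:14] <- 300                             # homogeneous stripe
  mp <- matrix(TRUE, 24, 24)
  v <- gabor_energy_feature(px, mp, 1:24)
  expect_true(max(v$profile[10:14]) < min(v$profile[c(1:6, 19:24)]))
  expect_true(v$col %in% 10:14)

  flat <- gabor_energy_feature(matrix(300, 24, 24), mp, 1:24)
  expect_equal(flat$col, 12)                     # flat profile ties break to center

  tiny <- gabor_energy_feature(matrix(300, 4, 4), matrix(TRUE, 4, 4), 1:4)
  expect_null(tiny)                              # smaller than any kernel support
})

test_that("mirrored symmetry features find the symmetry axis and shift with it", {
  set.seed(5)
  half <- matrix(rnorm(20 * 10, 300, 30), 20, 10)
  px <- cbind(half, matrix(250, 20, 1), half[, 10:1])
  mp <- matrix(TRUE, 20, 21)
  v <- mirrored_symmetry_features(px, mp, 1:21)
  nm <- vapply(v, `[[`, character(1), "feature")
  mse <- v[[which(nm == "mse_sym")]]; mgs <- v[[which(nm == "mgs_sym")]]
  expect_equal(mse$col, 11); expect_equal(mse$profile[11], 0)
  expect_equal(mgs$col, 11)

  # translation equivariance: padding 3 columns on the left shifts the votes
  px3 <- cbind(matrix(300, 20, 3), px)
  mp3 <- matrix(TRUE, 20, 24)
  v3 <- mirrored_symmetry_features(px3, mp3, 1:24)
  nm3 <- vapply(v3, `[[`, character(1), "feature")
  expect_equal(v3[[which(nm3 == "mse_sym")]]$col, 14)
})

test_that("symmetry profiles match an independent double loop", {
  set.seed(6)
  W <- 13
  px <- matrix(runif(15 * W, 100, 400), 15, W)
  mp <- matrix(TRUE, 15, W)
  v <- mirrored_symmetry_features(px, mp, 1:W)
  nm <- vapply(v, `[[`, character(1), "feature")
  prof <- rep(NA_real_, W)
  for (j in 1:W) {
    K <- min(j - 1, W - j)
    if (K < 3) next
    acc <- c()
    for (k in 1:K) acc <- c(acc, (px[, j - k] - px[, j + k])^2)
    prof[j] <- mean(acc)
  }
  expect_equal(v[[which(nm == "mse_sym")]]$profile, prof, tolerance = 1e-12)
})

test_that("votes are combined by the lower median", {
  mkv <- function(cols) lapply(cols, function(cc) list(feature = "x", col = cc))
  expect_equal(estimate_roi_control_point(mkv(c(50, 51, 49, 50, 52, 48, 70, 50)),
                                          c(10, 29))[["col"]], 50)
  expect_equal(estimate_roi_control_point(mkv(42), c(10, 29))[["col"]], 42)
  expect_equal(estimate_roi_control_point(mkv(c(40, 44)), c(10, 29))[["col"]], 40)
  expect_equal(estimate_roi_control_point(mkv(42), c(10, 29))[["row"]], 19.5)
  expect_null(estimate_roi_control_point(list(), c(10, 29)))
})

test_that("feature votes are invariant to affine intensity changes", {
  ph <- generate_phantom(small_spec(seed = 7))
  band <- extract_midline_band(96, 1)
  px <- ph$volume$data[3, 31:50, band]
  mp <- matrix(TRUE, nrow(px), ncol(px))        # mask-complete ROI
  base <- column_profile_features(px, mp, band)
  base_sym <- mirrored_symmetry_features(px, mp, band)
  for (ab in list(c(0.5, -20), c(2, 100))) {
    px2 <- ab[1] * px + ab[2]
    v2 <- column_profile_features(px2, mp, band)
    s2 <- mirrored_symmetry_features(px2, mp, band)
    nm <- vapply(base, `[[`, character(1), "feature")
    nm2 <- vapply(v2, `[[`, character(1), "feature")
    for (f in c("int_sum", "int_rms")) {
      expect_equal(v2[[which(nm2 == f)]]$col, base[[which(nm == f)]]$col)
    }
    expect_equal(s2[[1]]$col, base_sym[[1]]$col)  # mse_sym
  }
})

test_that("cross-slice repair flags and replaces stray points", {
  mkgrid <- function(cols) {
    S <- length(cols)
    structure(list(col = matrix(cols, S, 1), row = matrix(50, S, 1),
                   flag = matrix("ok", S, 1), cerebral = rep(TRUE, S),
                   band = 41:60, votes = NULL, spacing = c(3, 1, 1)),
              class = "control_point_grid")
  }
  # MAD = 0 here, so the 3 px absolute fallback flags the 90
  g <- refine_across_slices(mkgrid(c(50, 50, 51, 49, 50, 90, 50)))
  expect_equal(g$flag[6, 1], "repaired")
  expect_equal(g$col[6, 1], 50)

  g2 <- refine_across_slices(mkgrid(rep(47, 6)))
  expect_true(all(g2$flag == "ok"))

  g3 <- refine_across_slices(mkgrid(c(40, 42, 44, 46, 48)))  # trend, not outliers
  expect_true(all(g3$flag == "ok"))
  expect_equal(g3$col[, 1], c(40, 42, 44, 46, 48))

  # boundary slice: repaired from its single neighbor
  g4 <- refine_across_slices(mkgrid(c(90, 50, 51, 49, 50, 50, 50)))
  expect_equal(g4$flag[1, 1], "repaired")
  expect_equal(g4$col[1, 1], 50)
})

test_that("repair never moves unflagged points and interpolates flagged ones", {
  set.seed(8)
  for (rep in 1:20) {
    S <- 8
    cols <- 50 + runif(S, -0.2, 0.2)
    s0 <- sample(2:(S - 1), 1)
    corrupted <- cols; corrupted[s0] <- cols[s0] + sample(c(-40, 40), 1)
    g <- structure(list(col = matrix(corrupted, S, 1), row = matrix(50, S, 1),
                        flag = matrix("ok", S, 1), cerebral = rep(TRUE, S),
                        band = 41:60, votes = NULL, spacing = c(3, 1, 1)),
                   class = "control_point_grid")
    out <- refine_across_slices(g)
    expect_equal(out$flag[s0, 1], "repaired")
    expect_lte(abs(out$col[s0, 1] - mean(cols[c(s0 - 1, s0 + 1)])), 1)
    untouched <- out$flag[, 1] == "ok"
    expect_equal(out$col[untouched, 1], corrupted[untouched])
  }
})

test_that("control points track the phantom fissure before and after repair", {
  ph <- generate_phantom(phantom_spec(seed = 9))
  grid <- estimate_control_points(ph$volume)
  pts <- tidy(grid)
  err <- abs(pts$col - 64.5)
  expect_gte(mean(err <= 2), 0.9)
  refined <- refine_across_slices(grid)
  pts2 <- tidy(refined)
  expect_true(all(abs(pts2$col - 64.5) <= 3))
})
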