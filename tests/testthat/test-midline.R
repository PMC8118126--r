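test_that("midline fitting recovers representable curves", {
  rows <- seq(11, 111, by = 20)
  # linear control points: the monotone interpolant is exact, so is the fit
  lin <- cbind(rows, 80 + 0.05 * (rows - 1))
  f <- fit_slice_midline(lin, rows_eval = rows)
  expect_lt(max(abs(f$m - lin[, 2])), 1e-9)

  # exact quadratic: monotone Hermite slopes are only near-exact, the LS
  # cubic over its samples reproduces the control points to ~5e-3 px
  quad <- cbind(rows, 100 + 0.01 * (rows - 1) + 1e-4 * (rows - 1)^2)
  f2 <- fit_slice_midline(quad, rows_eval = rows)
  expect_lt(max(abs(f2$m - quad[, 2])), 0.01)

  # single point: vertical line fallback
  f3 <- fit_slice_midline(cbind(50, 98), rows_eval = 1:100)
  expect_true(all(f3$m == 98))

  expect_error(fit_slice_midline(cbind(numeric(0), numeric(0)), 1:10),
               "no control points")
})

test_that("fitted midline stays within 2 px of a cubic phantom fissure", {
  ph <- generate_phantom(phantom_spec(fissure_poly = c(62.5, 0.08, -1.2e-3, 4e-6),
                                      seed = 1))
  res <- estimate_volume_midline(ph$volume)
  # evaluated over the control-point span; beyond it the cubic extrapolates
  for (s in which(res$cerebral)) {
    sp <- range(res$grid$row[s, ], na.rm = TRUE)
    rows_in <- sp[1]:sp[2]
    ct <- fissura:::polyval0(ph$truth$poly[s, ], rows_in - 1)
    mm <- fissura:::polyval0(res$midlines[[s]]$coef, rows_in - 1)
    expect_lte(max(abs(mm - ct)), 2)
  }
})

test_that("hemisphere separation is an exact partition with the half-open rule", {
  ph <- generate_phantom(small_spec(seed = 2))
  res <- estimate_volume_midline(ph$volume)
  h <- res$hemispheres
  expect_false(any(h$left & h$right))
  expect_identical(h$left | h$right, ph$volume$mask)

  # fractional midline: the voxel at ceil(m) goes right
  vol <- flair_volume(array(300, c(5, 64, 64)), c(3, 1, 1),
                      mask = array(TRUE, c(5, 64, 64)))
  ml <- list(m = rep(30.4, 64), coef = c(30.4, 0, 0, 0), rows = 1:64)
  hp <- separate_hemispheres(vol, rep(list(ml), 5))
  expect_true(all(hp$right[, , 31]))
  expect_true(all(hp$left[, , 30]))
})

test_that("a straight midline splits a symmetric brain nearly evenly", {
  ph <- generate_phantom(phantom_spec(shape = c(6, 96, 95), seed = 3))
  res <- estimate_volume_midline(ph$volume)
  n_l <- sum(res$hemispheres$left); n_r <- sum(res$hemispheres$right)
  expect_lte(abs(n_l - n_r) / (n_l + n_r), 0.01)
})

test_that("the pipeline is deterministic end to end", {
  ph <- generate_phantom(small_spec(seed = 4))
  a <- estimate_volume_midline(ph$volume)
  b <- estimate_volume_midline(ph$volume)
  expect_identical(a$hemispheres$left, b$hemispheres$left)
  expect_identical(a$midlines, b$midlines)
})

test_that("per-slice fitting adapts to torque where a planar fit cannot", {
  S <- 10
  P <- cbind(64.5 + seq(-2, 2, length.out = S), 0.04, -8e-4,
             seq(1.5e-6, 4.5e-6, length.out = S))
  ph <- generate_phantom(phantom_spec(fissure_poly = P, seed = 5))
  res <- estimate_volume_midline(ph$volume)
  m <- evaluate_midline(res, ph$truth, ph$volume$spacing)
  expect_lte(m$mad_px, 1.5)

  # fitted polynomials genuinely differ across slices
  cf <- t(vapply(which(res$cerebral), function(s) res$midlines[[s]]$coef, numeric(4)))
  expect_gt(max(apply(cf, 2, function(x) diff(range(x)))), 0)
  expect_gt(nrow(unique(round(cf, 6))), 1)

  # best single vertical plane (oracle over all constant columns) is worse
  best_planar <- Inf
  for (cand in seq(55, 75, by = 0.25)) {
    tot <- 0; n <- 0
    for (s in which(res$cerebral)) {
      rows_s <- res$midlines[[s]]$rows
      ct <- fissura:::polyval0(ph$truth$poly[s, ], rows_s - 1)
      tot <- tot + mean(abs(cand - ct)); n <- n + 1
    }
    best_planar <- min(best_planar, tot / n)
  }
  expect_gt(best_planar, m$mad_px)
})

test_that("slices without control points inherit a midline and warn", {
  ph <- generate_phantom(small_spec(seed = 6))
  # drop brain tissue from the band on one cerebral slice to starve the ROIs
  res <- estimate_volume_midline(ph$volume)
  expect_false(any(vapply(res$midlines[res$cerebral], is.null, logical(1))))
  # tidy summary has one row per slice
  td <- tidy(res)
  expect_equal(nrow(td), dim(ph$volume$data)[1])
  expect_true(all(td$n_points[td$cerebral] >= 1))
})

test_that("median voting keeps the midline accurate under lesion load", {
  les <- lapply(3:6, function(s) list(slice = s, row = 55, col = 72,
                                      radius = 6, intensity = 450))
  ph <- generate_phantom(phantom_spec(lesions = les, seed = 8))
  res <- estimate_volume_midline(ph$volume)
  m <- evaluate_midline(res, ph$truth, ph$volume$spacing)
  expect_lte(m$mad_px, 1.5)
})

test_that("midline results serialize to disk", {
  ph <- generate_phantom(small_spec(seed = 7))
  res <- estimate_volume_midline(ph$volume)
  dir <- withr::local_tempdir()
  paths <- write_midline_result(res, ph$volume, dir, "t")
  expect_true(all(file.exists(paths)))
  pts <- read.csv(paths[["midline_csv"]])
  expect_true(all(c("slice", "row", "col") %in% names(pts)))
})
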