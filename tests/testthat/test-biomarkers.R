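test_that("NABM mask keeps the band and drops CSF and lesions", {
  arr <- array(300, c(5, 64, 64))
  arr[1, 1, 1] <- 100; arr[1, 1, 2] <- 250; arr[1, 1, 3] <- 500
  vol <- flair_volume(arr, c(3, 1, 1), mask = array(TRUE, c(5, 64, 64)))
  nm <- nabm_mask(vol)
  expect_false(nm[1, 1, 1]); expect_true(nm[1, 1, 2]); expect_false(nm[1, 1, 3])

  les <- list(list(slice = 3, row = 40, col = 80, radius = 5, intensity = 450))
  ph <- generate_phantom(phantom_spec(lesions = les, seed = 1))
  nm2 <- nabm_mask(ph$volume)
  expect_false(any(nm2 & ph$volume$data > 400))

  # generated NABM fraction recovered within 2%
  ph3 <- generate_phantom(phantom_spec(seed = 3))
  frac <- sum(nabm_mask(ph3$volume)) / sum(ph3$volume$mask)
  expect_lt(abs(frac - ph3$truth$nabm_fraction), 0.02)
})

test_that("LBP codes follow the tie and ordering conventions", {
  const <- matrix(300, 11, 11)
  m <- lbp_map(const)
  expect_true(all(m[4:8, 4:8] == 255))        # ties (>=) set every bit
  expect_true(all(is.na(m[1:3, ])))           # window must fit inside

  peak <- matrix(100, 11, 11); peak[6, 6] <- 500
  expect_equal(lbp_map(peak)[6, 6], 0)        # center brighter than every neighbor

  expect_error(lbp_map(matrix(1, 5, 5)), "smaller")
})

test_that("LBP matches an independent per-pixel loop on random patches", {
  set.seed(2)
  for (rep in 1:3) {
    p <- matrix(runif(11 * 11, 100, 400), 11, 11)
    expect_equal(lbp_map(p), oracle_lbp(p))
  }
})

test_that("pixel-wise averaging uses only contributing slices", {
  one <- matrix(c(1, NA, 3, 4), 2, 2)
  avg1 <- pixelwise_average(list(one))
  expect_equal(avg1$avg, one)

  a <- matrix(10, 2, 2); b <- matrix(20, 2, 2); c <- matrix(NA_real_, 2, 2)
  a[2, 2] <- NA; c[1, 1] <- 30
  out <- pixelwise_average(list(a, b, c))
  expect_equal(out$avg[1, 2], 15)             # in 2 of 3 slices: (10+20)/2
  expect_equal(out$avg[1, 1], 20)             # (10+20+30)/3
  expect_equal(out$avg[2, 2], 20)             # only slice b
  expect_equal(out$coverage[1, 1], 3L)

  # loop oracle over a random stack
  set.seed(3)
  maps <- lapply(1:4, function(i) {
    m <- matrix(runif(36, 0, 255), 6, 6)
    m[runif(36) < 0.3] <- NA
    m
  })
  got <- pixelwise_average(maps)
  for (r in 1:6) for (cc in 1:6) {
    v <- vapply(maps, function(m) m[r, cc], numeric(1))
    v <- v[!is.na(v)]
    if (length(v)) expect_equal(got$avg[r, cc], mean(v)) else expect_true(is.na(got$avg[r, cc]))
  }
})

test_that("texture features take closed-form values on degenerate maps", {
  flat <- pixelwise_average(list(matrix(42, 12, 12)))
  expect_warning(expect_warning(f <- texture_features(flat), "constant"),
                 "degenerate")
  expect_equal(f[["mean"]], 42); expect_equal(f[["median"]], 42)
  expect_equal(f[["variance"]], 0)
  expect_equal(f[["skewness"]], 0); expect_equal(f[["kurtosis"]], 0)
  expect_equal(f[["energy"]], 1); expect_equal(f[["contrast"]], 0)
  expect_equal(f[["homogeneity"]], 1); expect_equal(f[["entropy"]], 0)
})

test_that("checkerboard contrast equals the analytic co-occurrence value", {
  n <- 8
  cb <- outer(1:n, 1:n, function(r, c) (r + c) %% 2)
  img <- pixelwise_average(list(cb * 1))
  f <- suppressWarnings(texture_features(img))
  # axis pairs always differ by 31 levels, diagonal pairs never differ
  expect_equal(f[["contrast"]], 31^2 * n / (2 * n - 1), tolerance = 1e-12)
})

test_that("first-order features match the moment formulas", {
  set.seed(4)
  vals <- matrix(runif(400, 0, 255), 20, 20)
  f <- texture_features(pixelwise_average(list(vals)))
  v <- as.vector(vals); mu <- mean(v)
  expect_equal(f[["mean"]], mu)
  expect_equal(f[["median"]], median(v))
  expect_equal(f[["variance"]], mean((v - mu)^2))
  expect_equal(f[["skewness"]], mean((v - mu)^3) / mean((v - mu)^2)^1.5)
  expect_equal(f[["kurtosis"]], mean((v - mu)^4) / mean((v - mu)^2)^2)
})

test_that("feature asymmetry is the normalized absolute difference", {
  fl <- c(mean = 3, variance = 2); fr <- c(mean = 1, variance = 2)
  d <- asymmetry_features(fl, fr)
  expect_equal(d[["mean"]], 0.5)
  expect_equal(d[["variance"]], 0)
  expect_warning(z <- asymmetry_features(c(a = 0), c(a = 0)), "zero")
  expect_equal(z[["a"]], 0)
})

test_that("a mirrored phantom yields exactly zero feature asymmetry", {
  ph <- generate_phantom(small_spec(mirror = TRUE, seed = 5))
  b <- hemispheric_biomarkers(ph$volume, truth_hemis(ph), resample = FALSE)
  deltas <- unlist(b[grep("^delta_", names(b))])
  expect_identical(max(abs(deltas)), 0)
})

test_that("texture asymmetry grows with hemispheric degeneration", {
  probe <- function(tc, seed) {
    p <- generate_phantom(small_spec(texture_contrast = tc, seed = seed))
    b <- hemispheric_biomarkers(p$volume, truth_hemis(p), resample = FALSE)
    c(b$delta_variance, b$delta_contrast)
  }
  m <- vapply(c(1, 2), function(tc) {
    rowMeans(vapply(1:10, function(i) probe(tc, 400 + i), numeric(2)))
  }, numeric(2))
  expect_gt(m[1, 2], m[1, 1])   # delta variance
  expect_gt(m[2, 2], m[2, 1])   # delta contrast
})

test_that("group tests run ANOVA with Tukey HSD on Box-Cox data", {
  set.seed(6)
  vals <- abs(rnorm(30, 0.1, 0.03))
  df <- data.frame(diagnosis = rep(c("A", "B"), each = 30),
                   delta_variance = c(vals, vals))
  gt <- group_tests(df, "delta_variance")
  expect_s3_class(gt, "fissura_grouptest")
  expect_equal(tidy(gt)$estimate, 0)
  expect_gt(tidy(gt)$adj.p.value, 0.99)
  expect_true(is.finite(glance(gt)$statistic))

  # separated groups are detected
  df2 <- data.frame(diagnosis = rep(c("SCI", "MCI", "AD"), each = 30),
                    delta_variance = c(abs(rnorm(30, 0.05, 0.02)),
                                       abs(rnorm(30, 0.12, 0.02)),
                                       abs(rnorm(30, 0.20, 0.02))))
  gt2 <- group_tests(df2, "delta_variance")
  expect_lt(glance(gt2)$p.value, 0.001)
  expect_equal(nrow(tidy(gt2)), 3)

  dfz <- data.frame(diagnosis = rep(c("A", "B"), each = 5),
                    delta_variance = c(rep(0.1, 5), abs(rnorm(5, 0.2, 0.01))))
  expect_error(group_tests(dfz, "delta_variance"), "zero within-group.*A")
})

test_that("ANCOVA adjusts for covariates and a noise covariate changes little", {
  set.seed(7)
  n <- 100
  df <- data.frame(diagnosis = rep(c("SCI", "MCI", "AD"), each = n),
                   age = runif(3 * n, 55, 85),
                   sex = sample(c("F", "M"), 3 * n, replace = TRUE),
                   delta_contrast = abs(c(rnorm(n, 0.06, 0.03),
                                          rnorm(n, 0.09, 0.03),
                                          rnorm(n, 0.11, 0.03))))
  plain <- group_tests(df, "delta_contrast")
  aged <- group_tests(df, "delta_contrast", covariate = "age")
  sexed <- group_tests(df, "delta_contrast", covariate = "sex")
  f0 <- glance(plain)$statistic
  expect_lt(abs(glance(aged)$statistic - f0) / f0, 0.1)
  expect_lt(abs(glance(sexed)$statistic - f0) / f0, 0.1)
  expect_true(is.finite(glance(aged)$covariate_p.value))
  expect_equal(nrow(tidy(aged)), 3)
})
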