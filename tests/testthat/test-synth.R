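test_that("ring simulation point counts follow the analytic Poisson means", {
  gt <- ground_truth_pattern("ring")
  expect_equal(gt$area_high, pi * (30^2 - 20^2))
  counts <- t(vapply(1:50, function(s) {
    sim <- simulate_pattern(gt, seed = s)
    c(high = sum(sim$labels == "high"), bg = sum(sim$labels == "bg"))
  }, numeric(2)))
  mu_high <- gt$lambda_high * gt$area_high
  mu_bg <- gt$lambda_bg * (gt$window$area - gt$area_high)
  # mean of 50 Poisson draws: 3 sd of the Monte-Carlo mean
  expect_lt(abs(mean(counts[, "high"]) - mu_high), 3 * sqrt(mu_high / 50))
  expect_lt(abs(mean(counts[, "bg"]) - mu_bg), 3 * sqrt(mu_bg / 50))
  # all simulated points respect their region labels
  sim <- simulate_pattern(gt, seed = 1)
  hi <- sim$labels == "high"
  expect_true(all(gt$in_high(sim$spp$x[hi], sim$spp$y[hi])))
  expect_true(!any(gt$in_high(sim$spp$x[!hi], sim$spp$y[!hi])))
})

test_that("the dominant-circle geometry has a 16:1 area ratio and empty high regions stay empty", {
  gt <- ground_truth_pattern("circle_plus_four")
  ratio <- (pi * gt$geometry$r_central^2) / (pi * gt$geometry$r_small^2)
  expect_identical(ratio, 16)
  gt0 <- ground_truth_pattern("ring", lambda_high = 0)
  sim <- simulate_pattern(gt0, seed = 2)
  expect_equal(sum(sim$labels == "high"), 0)
})

test_that("simulated marks reproduce the 2.3 high/background mean intensity ratio", {
  gt <- ground_truth_pattern("central_circle")
  ratios <- vapply(1:20, function(s) {
    sim <- simulate_pattern(gt, seed = s)
    mean(sim$spp$marks[sim$labels == "high"]) /
      mean(sim$spp$marks[sim$labels == "bg"])
  }, numeric(1))
  expect_equal(mean(ratios), 2.3, tolerance = 0.05)
})

test_that("generators are seed-deterministic", {
  gt <- ground_truth_pattern("five_circles")
  a <- simulate_pattern(gt, seed = 33)
  b <- simulate_pattern(gt, seed = 33)
  expect_identical(a$spp$x, b$spp$x)
  expect_identical(a$spp$marks, b$spp$marks)
  s <- a$spp
  expect_identical(suppressWarnings(add_gaussian_noise(s, k = 1, seed = 4)$marks),
                   suppressWarnings(add_gaussian_noise(s, k = 1, seed = 4)$marks))
  expect_identical(add_intensity_artifacts(s, 5, seed = 4)$x,
                   add_intensity_artifacts(s, 5, seed = 4)$x)
})

test_that("Gaussian noise has the stated moments and respects clipping", {
  w <- square_window(100)
  set.seed(10)
  s <- spot_spp(runif(1e4, 0, 100), runif(1e4, 0, 100),
                rep(10000, 1e4), w, check = FALSE)
  # k = 0: Poisson-like noise with sd sqrt(mu); no clipping at this scale
  noisy <- add_gaussian_noise(s, k = 0, seed = 5)
  added <- noisy$marks - s$marks
  expect_equal(mean(added), 10000, tolerance = 3 * 100 / sqrt(1e4) / 10000)
  expect_equal(sd(added), sqrt(10000), tolerance = 0.05)
  # heavy noise is clipped at zero with a warning
  s2 <- spot_spp(runif(500, 0, 100), runif(500, 0, 100),
                 rlnorm(500, 5, 0.5), w, check = FALSE)
  expect_warning(n2 <- add_gaussian_noise(s2, k = 10, seed = 6), "clipped")
  expect_true(all(n2$marks >= 0))
  expect_error(add_gaussian_noise(s2, k = -1, seed = 1), ">= 0")
})

test_that("interference lands exactly at MOI + 2 sigma_G and spares distant windows", {
  set.seed(20)
  coords <- expand.grid(x = 0:9, y = 0:9)
  moi <- 544.3009
  sg <- 0.002
  vals <- matrix(rlnorm(100, 5, 0.5), ncol = 1)
  pm <- peak_matrix(coords, moi, vals)
  cont <- add_interference(pm, moi, sg, seed = 3)
  expect_equal(length(cont$mz), 2)
  expect_equal(cont$mz[2], moi + 2 * sg)
  expect_equal(as.numeric(cont$values[, 1]), as.numeric(pm$values[, 1]))
  # an interferent parked outside the +-3 sigma support leaves the
  # gaussian-weighted image untouched
  cont4 <- add_interference(pm, moi, sg, offset_sigmas = 4, seed = 3)
  win <- make_window(moi, sg * 2 * sqrt(2 * log(2)))
  img_clean <- spp_to_raster(build_spp(pm, win, "gaussian"))$values
  img4 <- spp_to_raster(build_spp(cont4, win, "gaussian"))$values
  expect_equal(img4, img_clean)
})

test_that("gaussian weighting beats uniform weighting under proximal interference", {
  # MSE against the clean image, across seeds
  set.seed(30)
  coords <- expand.grid(x = 0:19, y = 0:19)
  moi <- 544.3009
  sg <- 0.002
  win <- make_window(moi, sg * 2 * sqrt(2 * log(2)))
  vals <- matrix(rlnorm(400, 5, 0.5), ncol = 1)
  pm <- peak_matrix(coords, moi, vals)
  clean <- spp_to_raster(build_spp(pm, win, "gaussian"))$values
  clean_u <- spp_to_raster(build_spp(pm, win, "uniform"))$values
  mse <- function(a, b) mean((a - b)^2, na.rm = TRUE)
  wins <- vapply(1:20, function(s) {
    cont <- add_interference(pm, moi, sg, offset_sigmas = 2, seed = s)
    g <- spp_to_raster(build_spp(cont, win, "gaussian"))$values
    u <- spp_to_raster(build_spp(cont, win, "uniform"))$values
    mse(g, clean) < mse(u, clean_u)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("intensity artifacts hit exactly the requested number of pixels", {
  set.seed(40)
  coords <- expand.grid(x = 0:9, y = 0:9)
  pm <- peak_matrix(coords, 500, matrix(rlnorm(100, 5, 0.5), ncol = 1))
  mx <- max(pm$values)
  cont <- add_intensity_artifacts(pm, n_pixels = 10, seed = 2, mz = 500)
  expect_equal(sum(as.numeric(cont$values) > mx), 10)
  expect_true(all(as.numeric(cont$values)[as.numeric(cont$values) > mx] >= mx + mx))
  ident <- add_intensity_artifacts(pm, n_pixels = 0, seed = 2, mz = 500)
  expect_equal(as.matrix(ident$values), as.matrix(pm$values), ignore_attr = TRUE)
  expect_error(add_intensity_artifacts(pm, n_pixels = 101, seed = 2, mz = 500),
               "exceeds")
  # point-pattern flavor adds artifact points with marks above the old maximum
  s <- small_uniform_spp(50, side = 10)
  sa <- add_intensity_artifacts(s, n_pixels = 7, seed = 3)
  expect_equal(sa$n, 57)
  expect_equal(sum(sa$marks > max(s$marks)), 7)
})

test_that("Dice coefficient matches hand computations", {
  a <- matrix(FALSE, 4, 4); b <- a
  a[1, 1:4] <- TRUE                 # |A| = 4
  b[1, 2:4] <- TRUE; b[2, 1:3] <- TRUE  # |B| = 6, overlap 3
  expect_equal(dice(a, b), 2 * 3 / (4 + 6))
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, matrix(FALSE, 4, 4)), 0)
  expect_equal(dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  expect_error(dice(a, matrix(FALSE, 3, 3)), "grids differ")
})

test_that("stability scan needs at least two iterations and reports DSC per run", {
  s <- small_uniform_spp(n = 200, side = 30)
  expect_error(stability_scan(s, n_iter = 1), "at least 2")
  st <- stability_scan(s, n_iter = 3, base_seed = 2, h = 2)
  expect_length(st$dsc_hot, 3)
  expect_equal(st$dsc_hot[1], 1)
  expect_length(st$hot_frac, 3)
})

test_that("cross-tissue case simulators produce the advertised structures", {
  for (cs in 1:3) {
    sim <- simulate_ct_cases(cs, seed = 8)
    expect_s3_class(sim$test, "spot_spp")
    expect_s3_class(sim$ref, "spot_spp")
    expect_true(all(sim$test$marks >= 0))
  }
  s1 <- simulate_ct_cases(1, seed = 8)
  s3 <- simulate_ct_cases(3, seed = 8)
  # case 1 has elevated marks inside the structure, case 3 does not
  hi1 <- s1$truth$in_high(s1$test$x, s1$test$y)
  expect_gt(mean(s1$test$marks[hi1]), 1.5 * mean(s1$test$marks[!hi1]))
  hi3 <- s3$truth$in_high(s3$test$x, s3$test$y)
  expect_lt(abs(mean(s3$test$marks[hi3]) - mean(s3$test$marks[!hi3])),
            0.1 * mean(s3$test$marks))
  expect_error(simulate_ct_cases(4), "1, 2 or 3")
})
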