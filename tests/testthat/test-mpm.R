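test_that("CSR generation preserves count, density, and the mark multiset", {
  s <- small_uniform_spp(n = 50)
  csr <- generate_csr(s, seed = 1)
  expect_equal(csr$n, s$n)
  expect_equal(csr$lambda, s$lambda)
  expect_equal(sort(csr$marks), sort(s$marks))
  expect_true(all(in_window(csr$window, csr$x, csr$y)))
  # same seed reproduces; different seed relocates
  csr2 <- generate_csr(s, seed = 1)
  expect_identical(csr$x, csr2$x)
  expect_identical(csr$marks, csr2$marks)
  csr3 <- generate_csr(s, seed = 2)
  expect_false(identical(csr$x, csr3$x))
  expect_error(generate_csr(spot_spp(numeric(0), numeric(0), numeric(0),
                                     square_window(5))),
               "empty")
})

test_that("CSR mean nearest-neighbor distance matches the Poisson expectation", {
  # closed-form oracle for a uniform process: E[NN distance] = 0.5 / sqrt(lambda)
  s <- small_uniform_spp(n = 300, side = 100)
  expected <- 0.5 / sqrt(s$lambda)
  mean_nn <- function(p) {
    d <- as.matrix(dist(cbind(p$x, p$y)))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  nn <- vapply(1:100, function(k) mean_nn(generate_csr(s, seed = k)), numeric(1))
  # small positive bias from window edges; 5% envelope covers it plus MC error
  expect_equal(mean(nn), expected, tolerance = 0.05)
})

test_that("KDE matches a brute-force double-loop oracle on a 20x20 grid", {
  s <- small_uniform_spp(n = 30, side = 20)
  for (h in c(1.5, 3)) {
    est <- kde_density(s, h)$raster$values
    brute <- matrix(0, 20, 20)
    for (i in 1:20) for (j in 1:20) {
      xc <- j - 0.5; yc <- i - 0.5
      num <- sum(s$marks * dnorm(xc - s$x, sd = h) * dnorm(yc - s$y, sd = h))
      den <- 0
      for (ii in 1:20) for (jj in 1:20) {
        den <- den + dnorm(xc - (jj - 0.5), sd = h) * dnorm(yc - (ii - 0.5), sd = h)
      }
      brute[i, j] <- num / den
    }
    brute <- brute / sum(brute)
    expect_lt(max(abs(est - brute)), 1e-6)
  }
})

test_that("KDE densities are normalized with the mode at an isolated point", {
  w <- square_window(15)
  s <- spot_spp(7.5, 7.5, 4, w)
  d <- kde_density(s, 2)
  expect_equal(sum(d$raster$values), 1, tolerance = 1e-9)
  peak <- which(d$raster$values == max(d$raster$values), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(8, 8))
  # two equal marks far apart -> two equal local maxima
  s2 <- spot_spp(c(3.5, 11.5), c(7.5, 7.5), c(4, 4), w)
  d2 <- kde_density(s2, 1.5)$raster$values
  expect_equal(d2[8, 4], d2[8, 12], tolerance = 1e-9)
  expect_error(kde_density(spot_spp(numeric(0), numeric(0), numeric(0), w), 2),
               "empty")
})

test_that("Moran's I agrees with the direct formula and has the expected signs", {
  # brute-force oracle over the full double sum with queen adjacency
  moran_oracle <- function(v) {
    n <- length(v)
    coords <- expand.grid(r = 1:nrow(v), c = 1:ncol(v))
    wsum <- 0; num <- 0
    vb <- mean(v)
    for (a in 1:n) for (b in 1:n) {
      if (a == b) next
      dr <- abs(coords$r[a] - coords$r[b]); dc <- abs(coords$c[a] - coords$c[b])
      if (dr <= 1 && dc <= 1) {
        wsum <- wsum + 1
        num <- num + (v[coords$r[a], coords$c[a]] - vb) * (v[coords$r[b], coords$c[b]] - vb)
      }
    }
    (n / wsum) * num / sum((v - vb)^2)
  }
  checker <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  expect_equal(morans_i(checker), moran_oracle(checker), tolerance = 1e-12)
  expect_lt(morans_i(checker), 0)
  halves <- cbind(matrix(0, 4, 2), matrix(1, 4, 2))
  expect_equal(morans_i(halves), moran_oracle(halves), tolerance = 1e-12)
  expect_gt(morans_i(halves), 0)
  expect_error(morans_i(matrix(5, 3, 3)), "constant image")
})

test_that("Kneedle picks the knee of a concave curve and falls back on linear ones", {
  h <- seq(1, 10, by = 0.5)
  y <- 1 - exp(-h)
  knee <- spotmap:::kneedle_knee(h, y)
  # independent discrete oracle: maximizer of the normalized difference curve
  xn <- (h - min(h)) / diff(range(h))
  yn <- (y - min(y)) / diff(range(y))
  oracle <- h[which.max(yn - xn)]
  expect_equal(knee, oracle)
  expect_true(knee >= 2 && knee <= 4)
  # linear curve: no knee, documented fallback with warning
  expect_true(is.na(spotmap:::kneedle_knee(h, 2 * h + 1)))
  expect_warning(fb <- spotmap:::select_knee(h, 2 * h + 1), "no knee")
  expect_true(fb %in% h)
})

test_that("Moran's I rises steeply before the knee and barely changes after", {
  for (seed in c(1, 2)) {
    gt <- ground_truth_pattern("central_circle", side = 60)
    sim <- simulate_pattern(gt, seed = seed)
    scan <- estimate_bandwidth(sim$spp)
    expect_true(scan$knee %in% scan$bandwidths)
    rng <- diff(range(scan$moran_i))
    before <- scan$bandwidths <= scan$knee
    # strictly increasing up to the knee ...
    expect_true(all(diff(scan$moran_i[before]) > 0))
    # ... and essentially flat beyond it (small changes of either sign)
    expect_true(all(abs(diff(scan$moran_i[!before])) < 0.05 * rng))
  }
})

test_that("p-value maps follow the normal null and the BH step-up procedure", {
  s <- small_uniform_spp(n = 200, side = 30)
  rho <- kde_density(s, 3)
  csr_rho <- kde_density(generate_csr(s, seed = 4), 3)
  pv <- pvalue_maps(rho, csr_rho)
  # a pixel at the null mean splits the tails at one half
  z <- (rho$raster$values - pv$mu_csr) / pv$sigma_csr
  at_mean <- which(abs(z) == min(abs(z), na.rm = TRUE))[1]
  expect_equal(pv$p_upr$values[at_mean] + pv$p_lwr$values[at_mean], 1)
  # raw tails sum to 1 everywhere; adjusted maps dominate raw maps
  fin <- is.finite(pv$p_upr$values)
  expect_equal(pv$p_upr$values[fin] + pv$p_lwr$values[fin], rep(1, sum(fin)))
  expect_true(all(pv$p_upr_adj$values[fin] >= pv$p_upr$values[fin] - 1e-12))
  expect_true(all(pv$p_lwr_adj$values[fin] >= pv$p_lwr$values[fin] - 1e-12))
  expect_true(all(pv$p_upr_adj$values[fin] <= 1))
})

test_that("BH adjustment matches the hand step-up oracle on the 4-value example", {
  p <- c(0.01, 0.02, 0.04, 0.05)
  # step-up oracle: p_(i) * m / i, cumulative minimum from the largest rank
  m <- length(p)
  adj_oracle <- rev(cummin(rev(p * m / seq_len(m))))
  expect_equal(adj_oracle, c(0.04, 0.04, 0.05, 0.05))
  expect_equal(p.adjust(p, "BH"), adj_oracle)
})

test_that("contours trace single pixels, disks, and disjoint blobs", {
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  polys <- extract_contours(m1)
  expect_length(polys, 1)
  expect_equal(polys[[1]]$x[1], polys[[1]]$x[length(polys[[1]]$x)])
  disk <- matrix(FALSE, 30, 30)
  ctr <- expand.grid(x = 1:30 - 0.5, y = 1:30 - 0.5)
  disk[(ctr$x - 15)^2 + (ctr$y - 15)^2 <= 100] <- TRUE
  pd <- extract_contours(disk)
  expect_length(pd, 1)
  expect_equal(shoelace_area(pd[[1]]), pi * 100, tolerance = 0.05)
  two <- matrix(FALSE, 10, 10); two[2:3, 2:3] <- TRUE; two[7:8, 7:8] <- TRUE
  expect_length(extract_contours(two), 2)
  expect_length(extract_contours(matrix(FALSE, 4, 4)), 0)
})

test_that("full maps keep tails disjoint and are monotone in alpha", {
  rf <- ring_fixture()
  res05 <- compute_mpm(rf$sim$spp, alpha = 0.05, h = 3, seed = 5)
  res01 <- compute_mpm(rf$sim$spp, alpha = 0.01, h = 3, seed = 5)
  expect_false(any(res05$hotspot_mask & res05$coldspot_mask))
  expect_true(all(res01$hotspot_mask <= res05$hotspot_mask))
  expect_true(all(res01$coldspot_mask <= res05$coldspot_mask))
  expect_gt(sum(res05$hotspot_mask), 0)
  # marks carried through unmodified
  expect_identical(res05$spp$marks, rf$sim$spp$marks)
})

test_that("the CSR density distribution approaches normality as bandwidth grows", {
  rf <- ring_fixture()
  csr <- generate_csr(rf$sim$spp, seed = 9)
  ks_stat <- vapply(c(1.5, 3, 8), function(h) {
    v <- kde_density(csr, h)$raster$values
    v <- v[is.finite(v)]
    z <- (v - mean(v)) / sd(v)
    suppressWarnings(ks.test(z, "pnorm"))$statistic
  }, numeric(1))
  expect_lt(ks_stat[2], ks_stat[1])
  expect_lt(ks_stat[3], ks_stat[1])
})
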