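test_that("mass window geometry follows the FWHM at the MOI m/z", {
  win <- make_window(400, 0.0048)
  expect_equal(win$sigma_g, 0.0048 / (2 * sqrt(2 * log(2))))
  expect_equal(diff(win$support), 6 * win$sigma_g)
  expect_equal(win$support[2] - 400, 3 * 0.0048 / 2.35482, tolerance = 1e-5)
  expect_equal(mean(win$support), 400)  # centered on the MOI
  # a larger FWHM gives a strictly wider support
  expect_gt(diff(make_window(400, 0.0096)$support), diff(win$support))
})

test_that("Gaussian weighting down-weights off-center peaks; uniform does not", {
  win <- make_window(400, 0.0048)
  sg <- win$sigma_g
  expect_equal(weighted_intensity(400, 10, win, "gaussian"), 10)
  expect_equal(weighted_intensity(400, 10, win, "uniform"), 10)
  expect_equal(weighted_intensity(400 + 2 * sg, 10, win, "gaussian"),
               10 * exp(-2), tolerance = 1e-8)
  expect_equal(weighted_intensity(400 + 2 * sg, 10, win, "uniform"), 10)
  # outside the +-3 sigma support both modes see nothing
  expect_equal(weighted_intensity(400 + 4 * sg, 10, win, "gaussian"), 0)
  expect_equal(weighted_intensity(400 + 4 * sg, 10, win, "uniform"), 0)
  expect_equal(weighted_intensity(numeric(0), numeric(0), win, "gaussian"), 0)
})

test_that("gaussian-weighted intensity never exceeds the uniform sum", {
  set.seed(8)
  win <- make_window(400, 0.0048)
  for (rep in 1:20) {
    mz <- 400 + runif(5, -4, 4) * win$sigma_g
    i <- runif(5, 0, 100)
    g <- weighted_intensity(mz, i, win, "gaussian")
    u <- weighted_intensity(mz, i, win, "uniform")
    expect_lte(g, u + 1e-12)
  }
  # equality iff every peak sits exactly at the center
  expect_equal(weighted_intensity(c(400, 400), c(3, 4), win, "gaussian"),
               weighted_intensity(c(400, 400), c(3, 4), win, "uniform"))
})

test_that("build_spp emits one point per detected pixel over the full tissue window", {
  win <- make_window(200.2, 0.0048)
  pm <- peak_matrix(data.frame(x = c(0, 1, 2), y = c(0, 0, 0)),
                    mz = c(100.1, 200.2),
                    values = matrix(c(1, 5,
                                      2, 0,
                                      3, 7), nrow = 3, byrow = TRUE))
  spp <- build_spp(pm, win)
  expect_equal(spp$n, 2)
  expect_equal(spp$window$area, 3)  # window includes the undetected pixel
  expect_equal(spp$lambda, 2 / 3)
  expect_equal(sort(spp$marks), c(5, 7))
  # marks are invariant to peak order within the window support
  win2 <- make_window(200.2, 0.1)  # wide window catching both columns
  s1 <- build_spp(pm, win2)
  pm_rev <- peak_matrix(pm$coords, pm$mz, pm$values)  # same content
  s2 <- build_spp(pm_rev, win2)
  expect_equal(s1$marks, s2$marks)
  # MOI absent everywhere -> empty pattern with warning
  expect_warning(empty <- build_spp(pm, make_window(900, 0.0048)), "not observed")
  expect_equal(empty$n, 0)
  expect_equal(empty$lambda, 0)
})

test_that("raster conversion round-trips grid-aligned patterns", {
  w <- spot_window(matrix(TRUE, 3, 4))
  s <- spot_spp(c(0.5, 2.5), c(1.5, 0.5), c(2, 5), w)
  img <- spp_to_raster(s)
  expect_equal(img$values[2, 1], 2)
  expect_equal(img$values[1, 3], 5)
  expect_equal(sum(is.finite(img$values)), 2)
  back <- raster_to_spp(img, w)
  o <- order(back$x)
  expect_equal(back$x[o], sort(s$x))
  expect_equal(back$marks[o][order(sort(s$x))], s$marks[order(s$x)])
  # NaN pixels emit no point
  img$values[1, 1] <- NaN
  expect_equal(raster_to_spp(img, w)$n, 2)
  # off-grid points refuse silent rasterization
  s_off <- spot_spp(1.25, 1.25, 1, w)
  expect_error(spp_to_raster(s_off), "not grid-aligned")
  expect_equal(spp_to_raster(s_off, nearest = TRUE)$values[2, 2], 1)
  # co-located points are summed when rasterized
  s_co <- spot_spp(c(0.5, 0.5), c(0.5, 0.5), c(2, 3), w)
  expect_equal(spp_to_raster(s_co)$values[1, 1], 5)
})

test_that("spatial expressions evaluate composite scores pixel-wise", {
  w <- spot_window(matrix(TRUE, 2, 2))
  mk <- function(m, x = c(0.5, 1.5), y = c(0.5, 0.5)) spot_spp(x, y, m, w)
  atp <- mk(c(2, 2)); adp <- mk(c(2, 2)); amp <- mk(c(1, 1))
  # adenylate energy charge (ATP + 0.5 ADP) / (ATP + ADP + AMP)
  ec <- suppressWarnings(
    eval_expression("(atp + 0.5*adp)/(atp + adp + amp)",
                    list(atp = atp, adp = adp, amp = amp)))
  expect_equal(ec$marks, c(0.6, 0.6))
  # adenylate kinase mass action ratio ATP*AMP/ADP^2
  mar <- suppressWarnings(
    eval_expression("atp*amp/(adp*adp)", list(atp = atp, adp = adp, amp = amp)))
  expect_equal(mar$marks, c(0.5, 0.5))
  # pixels missing in one operand are dropped
  y_part <- mk(5, x = 0.5, y = 0.5)
  r <- suppressWarnings(eval_expression("atp/y", list(atp = atp, y = y_part)))
  expect_equal(r$n, 1)
  expect_equal(r$marks, 2 / 5)
  # X + 0 equals X on common pixels
  same <- eval_expression("atp + 0", list(atp = atp))
  expect_equal(same$marks, atp$marks)
  expect_equal(same$x, atp$x)
  # unbound names and disallowed operators are rejected
  expect_error(eval_expression("atp + gtp", list(atp = atp)), "unbound operand 'gtp'|unbound operand name 'gtp'")
  expect_error(eval_expression("exp(atp)", list(atp = atp)), "not allowed")
  expect_warning(eval_expression("atp/adp", list(atp = atp, adp = adp)),
                 "division")
})

test_that("division by zero drops the pixel rather than propagating", {
  w <- spot_window(matrix(TRUE, 1, 2))
  num <- spot_spp(c(0.5, 1.5), c(0.5, 0.5), c(4, 6), w)
  den <- spot_spp(c(0.5, 1.5), c(0.5, 0.5), c(2, 0), w)
  r <- suppressWarnings(eval_expression("num/den", list(num = num, den = den)))
  expect_equal(r$n, 1)
  expect_equal(r$marks, 2)
})

test_that("point patterns validate their window membership and density", {
  w <- spot_window(matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2))
  expect_equal(w$area, 3)
  expect_error(spot_spp(0.5, 1.5, 1, w), "outside the tissue window")
  s <- spot_spp(c(0.5, 1.5), c(0.5, 1.5), c(1, 2), w)
  expect_equal(s$lambda, 2 / 3)
})
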