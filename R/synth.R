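#' Ground-truth geometry for simulated hotspot patterns
#'
#' The four simulated high-abundance geometries used for validation, each
#' placed in a square window of `side` length units: a single central
#' circle, five equidistant circles, a ring, and a dominant central circle
#' with four adjacent smaller ones (central/peripheral area ratio
#' \eqn{(20/5)^2 = 16} at the defaults). High-region and background point
#' densities default to 0.4 and 0.3 points per unit area.
#'
#' @param kind one of `"central_circle"`, `"five_circles"`, `"ring"`,
#'   `"circle_plus_four"`.
#' @param side window side length (default 100).
#' @param lambda_high,lambda_bg spatial point densities of the high-MOI
#'   region and the background.
#' @param r_outer,r_inner ring radii (defaults 30 and 20).
#' @param r_central,r_small central/peripheral radii for
#'   `circle_plus_four` (defaults 20 and 5) and circle radius for
#'   `central_circle` / `five_circles` (via `r_central` and `r_small`).
#' @param offset center-to-center distance of peripheral circles.
#' @return object of class `ground_truth` with the region membership
#'   function `in_high(x, y)`, the analytic high-region area `area_high`,
#'   the window, densities, and the rasterized `truth_mask`.
#' @export
ground_truth_pattern <- function(kind = c("central_circle", "five_circles",
                                          "ring", "circle_plus_four"),
                                 side = 100, lambda_high = 0.4, lambda_bg = 0.3,
                                 r_outer = 30, r_inner = 20,
                                 r_central = 20, r_small = 5,
                                 offset = 30) {
  kind <- match.arg(kind)
  if (lambda_high < 0 || lambda_bg < 0) stop("densities must be nonnegative")
  cx <- side / 2; cy <- side / 2
  d2 <- function(x, y, px, py) (x - px)^2 + (y - py)^2
  diag_off <- offset / sqrt(2)
  centers <- switch(kind,
    central_circle = cbind(cx, cy),
    five_circles = rbind(c(cx, cy),
                         c(cx - diag_off, cy - diag_off), c(cx + diag_off, cy - diag_off),
                         c(cx - diag_off, cy + diag_off), c(cx + diag_off, cy + diag_off)),
    ring = cbind(cx, cy),
    circle_plus_four = rbind(c(cx, cy),
                             c(cx - diag_off, cy - diag_off), c(cx + diag_off, cy - diag_off),
                             c(cx - diag_off, cy + diag_off), c(cx + diag_off, cy + diag_off)))
  in_high <- switch(kind,
    central_circle = function(x, y) d2(x, y, cx, cy) <= r_central^2,
    five_circles = function(x, y) {
      hit <- rep(FALSE, length(x))
      for (k in seq_len(nrow(centers))) {
        hit <- hit | d2(x, y, centers[k, 1], centers[k, 2]) <= r_small^2
      }
      hit
    },
    ring = function(x, y) {
      dd <- d2(x, y, cx, cy)
      dd <= r_outer^2 & dd >= r_inner^2
    },
    circle_plus_four = function(x, y) {
      hit <- d2(x, y, cx, cy) <= r_central^2
      for (k in 2:nrow(centers)) {
        hit <- hit | d2(x, y, centers[k, 1], centers[k, 2]) <= r_small^2
      }
      hit
    })
  area_high <- switch(kind,
    central_circle = pi * r_central^2,
    five_circles = 5 * pi * r_small^2,
    ring = pi * (r_outer^2 - r_inner^2),
    circle_plus_four = pi * r_central^2 + 4 * pi * r_small^2)
  window <- square_window(side)
  ctr <- window_centers(window)
  grid <- expand.grid(x = ctr$x, y = ctr$y)
  truth_mask <- matrix(in_high(grid$x, grid$y), nrow = window$ny, byrow = TRUE)
  structure(list(kind = kind, side = side, window = window,
                 lambda_high = lambda_high, lambda_bg = lambda_bg,
                 in_high = in_high, area_high = area_high,
                 truth_mask = truth_mask,
                 geometry = list(r_outer = r_outer, r_inner = r_inner,
                                 r_central = r_central, r_small = r_small,
                                 offset = offset, centers = centers)),
            class = "ground_truth")
}

# Default mark sampler: lognormal intensities (sdlog 0.5) with a
# high/background mean ratio of 2.3 and a background mean of 2000 counts,
# a stand-in for intensities drawn from above/below the upper quartile of a
# real FTICR measurement.
default_intensity_model <- function(mean_bg = 2000, ratio = 2.3, sdlog = 0.5) {
  meanlog_bg <- log(mean_bg) - sdlog^2 / 2
  function(n, region) {
    ml <- if (region == "high") meanlog_bg + log(ratio) else meanlog_bg
    stats::rlnorm(n, meanlog = ml, sdlog = sdlog)
  }
}

# uniform points inside a region defined by a membership predicate
sample_region_points <- function(n, window, predicate) {
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(4L * (n - length(xs)), 64L)
    cx <- stats::runif(m, window$x0, window$x0 + window$nx)
    cy <- stats::runif(m, window$y0, window$y0 + window$ny)
    ok <- predicate(cx, cy)
    xs <- c(xs, cx[ok]); ys <- c(ys, cy[ok])
  }
  list(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

#' Simulate a marked point pattern from a ground-truth geometry
#'
#' Points are placed by homogeneous Poisson processes: a Poisson count with
#' mean \eqn{\Lambda_{high} A_{high}} uniform inside the high-abundance
#' region and \eqn{\Lambda_{bg} (A_{window} - A_{high})} uniform in the
#' background. Marks are drawn from `intensity_model(n, region)`
#' (`region` is `"high"` or `"bg"`); the default lognormal model gives a
#' high/background mean intensity ratio of ~2.3.
#'
#' @param truth a [ground_truth_pattern()].
#' @param intensity_model mark sampler `function(n, region)`; `NULL` for
#'   the default.
#' @param seed RNG seed.
#' @return object of class `simulation_result`: `spp`, `truth`, `seed` and
#'   per-point `labels` (`"high"`/`"bg"`).
#' @export
simulate_pattern <- function(truth, intensity_model = NULL, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(intensity_model)) intensity_model <- default_intensity_model()
  with_seed(seed, {
    w <- truth$window
    n_high <- stats::rpois(1, truth$lambda_high * truth$area_high)
    n_bg <- stats::rpois(1, truth$lambda_bg * (w$area - truth$area_high))
    hi <- sample_region_points(n_high, w, truth$in_high)
    bg <- sample_region_points(n_bg, w, function(x, y) !truth$in_high(x, y))
    marks <- c(intensity_model(n_high, "high"), intensity_model(n_bg, "bg"))
    spp <- spot_spp(c(hi$x, bg$x), c(hi$y, bg$y), marks, w, check = FALSE)
    structure(list(spp = spp, truth = truth, seed = seed,
                   labels = rep(c("high", "bg"), c(n_high, n_bg))),
              class = "simulation_result")
  })
}

# ---- noise injections -----------------------------------------------------

#' Add Gaussian intensity noise
#'
#' Draws per-signal noise from a normal distribution whose mean equals the
#' MOI's mean intensity \eqn{\mu_{MOI}} and whose standard deviation is
#' \eqn{\sigma_k}: \eqn{\sigma_0 = \sqrt{\mu_{MOI}}} (Poisson-like noise)
#' for `k = 0`, and \eqn{\sigma_k = k\,\sigma_{MOI}} for `k >= 1`. Noisy
#' intensities are clipped at zero (the clipped fraction is reported in a
#' warning when it is nonzero).
#'
#' For a point pattern the noise is added to every point's mark. For a peak
#' matrix it is added to the MOI column (nearest to `mz`) in every pixel,
#' including pixels where the MOI was absent.
#'
#' @param x a [spot_spp()] or [peak_matrix()].
#' @param k noise-dispersion multiplier (`k >= 0`).
#' @param seed RNG seed.
#' @param mz MOI m/z (peak-matrix method only).
#' @param ... passed between methods.
#' @return an object of the same class as `x`.
#' @export
add_gaussian_noise <- function(x, k = 1, seed = NULL, ...) {
  UseMethod("add_gaussian_noise")
}

noise_sd <- function(k, mu, sigma) {
  if (k < 0) stop("'k' must be >= 0")
  if (k == 0) sqrt(mu) else k * sigma
}

#' @rdname add_gaussian_noise
#' @export
add_gaussian_noise.spot_spp <- function(x, k = 1, seed = NULL, ...) {
  if (x$n == 0) return(x)
  mu <- mean(x$marks); sigma <- stats::sd(x$marks)
  sd_k <- noise_sd(k, mu, sigma)
  with_seed(seed, {
    noisy <- x$marks + stats::rnorm(x$n, mean = mu, sd = sd_k)
    clipped <- noisy < 0
    if (any(clipped)) {
      warnf("%.1f%% of noisy marks clipped at zero", 100 * mean(clipped))
      noisy[clipped] <- 0
    }
    spot_spp(x$x, x$y, noisy, x$window, check = FALSE)
  })
}

#' @rdname add_gaussian_noise
#' @export
add_gaussian_noise.msi_peaks <- function(x, k = 1, seed = NULL, mz = NULL, ...) {
  if (is.null(mz)) stop("'mz' of the MOI column is required for peak matrices")
  col <- which.min(abs(x$mz - mz))
  v <- as.numeric(x$values[, col])
  present <- v > 0
  if (!any(present)) stop("MOI column is empty; nothing to contaminate")
  mu <- mean(v[present]); sigma <- stats::sd(v[present])
  sd_k <- noise_sd(k, mu, sigma)
  with_seed(seed, {
    noisy <- v + stats::rnorm(length(v), mean = mu, sd = sd_k)
    noisy[noisy < 0] <- 0
    vals <- x$values
    vals[, col] <- noisy
    peak_matrix(x$coords, x$mz, vals, pixel_size_um = x$pixel_size_um,
                polarity = x$polarity)
  })
}

#' Spike an interfering peak near the MOI m/z
#'
#' Adds a new peak column at exactly `m_moi + offset_sigmas * sigma_g`
#' (default two envelope widths above the MOI) with intensities drawn for
#' every pixel from a normal distribution matching the MOI's intensity mean
#' and standard deviation (clipped at zero) — proximal background signal
#' that Gaussian mass-window weighting is designed to down-weight.
#'
#' @param pm a [peak_matrix()].
#' @param m_moi MOI m/z (Da).
#' @param sigma_g Gaussian envelope sd (Da).
#' @param offset_sigmas interferent offset in multiples of `sigma_g`
#'   (default 2).
#' @param seed RNG seed.
#' @return the contaminated [peak_matrix()].
#' @export
add_interference <- function(pm, m_moi, sigma_g, offset_sigmas = 2, seed = NULL) {
  stopifnot(inherits(pm, "msi_peaks"))
  target <- m_moi + offset_sigmas * sigma_g
  col <- which.min(abs(pm$mz - m_moi))
  v <- as.numeric(pm$values[, col])
  present <- v > 0
  if (!any(present)) stop("MOI column is empty; nothing to interfere with")
  mu <- mean(v[present]); sigma <- stats::sd(v[present])
  with_seed(seed, {
    intensities <- pmax(stats::rnorm(nrow(pm$coords), mu, sigma), 0)
    new_mz <- sort(c(pm$mz, target))
    vals <- cbind(pm$values, Matrix::Matrix(intensities, ncol = 1, sparse = TRUE))
    vals <- vals[, order(c(pm$mz, target)), drop = FALSE]
    peak_matrix(pm$coords, new_mz, vals, pixel_size_um = pm$pixel_size_um,
                polarity = pm$polarity)
  })
}

#' Spike single-pixel high-intensity artifacts
#'
#' Adds to `n_pixels` distinct randomly chosen pixels an intensity drawn
#' from a uniform rectangular distribution whose range far exceeds the MOI
#' intensity range: `Uniform(max, 10 * max)` of the pre-noise maximum —
#' the signature of tissue tears, matrix crystals or source contamination.
#'
#' For a peak matrix the artifact is added to the MOI column; for a point
#' pattern, artifact points are placed at the chosen pixel centers.
#'
#' @param x a [spot_spp()] or [peak_matrix()].
#' @param n_pixels number of affected pixels (default 10).
#' @param seed RNG seed.
#' @param mz MOI m/z (peak-matrix method only).
#' @param ... passed between methods.
#' @return an object of the same class as `x`.
#' @export
add_intensity_artifacts <- function(x, n_pixels = 10, seed = NULL, ...) {
  UseMethod("add_intensity_artifacts")
}

#' @rdname add_intensity_artifacts
#' @export
add_intensity_artifacts.msi_peaks <- function(x, n_pixels = 10, seed = NULL,
                                              mz = NULL, ...) {
  if (is.null(mz)) stop("'mz' of the MOI column is required for peak matrices")
  n_pix_total <- nrow(x$coords)
  if (n_pixels > n_pix_total) stop("'n_pixels' exceeds the number of pixels")
  if (n_pixels == 0) return(x)
  col <- which.min(abs(x$mz - mz))
  v <- as.numeric(x$values[, col])
  mx <- max(v)
  with_seed(seed, {
    pick <- sample.int(n_pix_total, n_pixels)
    v[pick] <- v[pick] + stats::runif(n_pixels, mx, 10 * mx)
    vals <- x$values
    vals[, col] <- v
    peak_matrix(x$coords, x$mz, vals, pixel_size_um = x$pixel_size_um,
                polarity = x$polarity)
  })
}

#' @rdname add_intensity_artifacts
#' @export
add_intensity_artifacts.spot_spp <- function(x, n_pixels = 10, seed = NULL, ...) {
  w <- x$window
  tissue <- which(w$mask)
  if (n_pixels > length(tissue)) stop("'n_pixels' exceeds the number of tissue pixels")
  if (n_pixels == 0) return(x)
  mx <- max(x$marks)
  with_seed(seed, {
    pick <- sample(tissue, n_pixels)
    i <- ((pick - 1L) %% w$ny) + 1L
    j <- ((pick - 1L) %/% w$ny) + 1L
    ax <- w$x0 + j - 0.5
    ay <- w$y0 + i - 0.5
    marks <- stats::runif(n_pixels, mx, 10 * mx)
    spot_spp(c(x$x, ax), c(x$y, ay), c(x$marks, marks), w, check = FALSE)
  })
}

# ---- evaluation -----------------------------------------------------------

#' Dice similarity coefficient of two binary masks
#'
#' \eqn{DSC = 2|A \cap B| / (|A| + |B|)}. Two empty masks are treated as
#' identical (DSC 1).
#'
#' @param mask_a,mask_b logical matrices on the same grid.
#' @return DSC in \[0, 1\].
#' @export
dice <- function(mask_a, mask_b) {
  if (inherits(mask_a, "spot_raster")) mask_a <- mask_a$values
  if (inherits(mask_b, "spot_raster")) mask_b <- mask_b$values
  if (!identical(dim(mask_a), dim(mask_b))) stop("mask grids differ")
  a <- mask_a & !is.na(mask_a); b <- mask_b & !is.na(mask_b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Stability of probabilistic maps across CSR redraws
#'
#' Repeats the full mapping `n_iter` times on the same pattern, each run
#' with a fresh CSR permutation (seeds `base_seed`, `base_seed + 1`, ...),
#' and reports the Dice overlap of each run's hotspot and coldspot masks
#' with the first run's, plus the per-run significant-area fractions. The
#' bandwidth is estimated once from the pattern and held fixed so the scan
#' isolates the CSR redraw variability.
#'
#' @param spp a nonempty [spot_spp()].
#' @param n_iter number of repeats (at least 2).
#' @param base_seed seed of the first iteration.
#' @param alpha significance level.
#' @param h bandwidth (`"auto"` estimates once via [estimate_bandwidth()]).
#' @return list with `dsc_hot`, `dsc_cold` (length `n_iter`, first = 1),
#'   `mean_dsc_hot`, `mean_dsc_cold`, `hot_frac`, `cold_frac`, `bandwidth`.
#' @export
stability_scan <- function(spp, n_iter = 20, base_seed = 1, alpha = 0.05,
                           h = "auto") {
  if (!is_count(n_iter) || n_iter < 2) stop("'n_iter' must be at least 2")
  if (identical(h, "auto")) h <- estimate_bandwidth(spp)$knee
  runs <- lapply(seq_len(n_iter) - 1L, function(k) {
    compute_mpm(spp, alpha = alpha, h = h, seed = base_seed + k)
  })
  ref <- runs[[1]]
  dsc_hot <- vapply(runs, function(r) dice(ref$hotspot_mask, r$hotspot_mask), numeric(1))
  dsc_cold <- vapply(runs, function(r) dice(ref$coldspot_mask, r$coldspot_mask), numeric(1))
  area <- spp$window$area
  list(dsc_hot = dsc_hot, dsc_cold = dsc_cold,
       mean_dsc_hot = mean(dsc_hot), mean_dsc_cold = mean(dsc_cold),
       hot_frac = vapply(runs, function(r) sum(r$hotspot_mask) / area, numeric(1)),
       cold_frac = vapply(runs, function(r) sum(r$coldspot_mask) / area, numeric(1)),
       bandwidth = h)
}

#' Simulate the three cross-tissue validation cases
#'
#' Paired test/reference patterns probing the two CT-MPM null hypotheses:
#' case 1 has a spatial high-density structure in the test tissue and test
#' marks drawn from a normal distribution shifted above the reference's
#' (both nulls rejected inside the structure); case 2 has no spatial
#' structure but shifted marks (spatial null accepted); case 3 has the
#' structure but marks identical in distribution to the reference
#' (intensity null accepted). Only case 1 should yield a non-empty
#' combined mask.
#'
#' @param case 1, 2 or 3.
#' @param seed RNG seed.
#' @param mean_test,mean_ref,sdev normal mark parameters: the shifted test
#'   mean, the reference mean, and the common sd.
#' @return list with `test` and `ref` [spot_spp()] patterns and the
#'   ground-truth geometry (`truth`, `NULL` for case 2).
#' @export
simulate_ct_cases <- function(case, seed = NULL, mean_test = 180,
                              mean_ref = 100, sdev = 20) {
  if (!case %in% 1:3) stop("'case' must be 1, 2 or 3")
  with_seed(seed, {
    truth <- ground_truth_pattern("ring")
    w <- truth$window
    ref_n <- stats::rpois(1, truth$lambda_bg * w$area)
    ref_pts <- sample_region_points(ref_n, w, function(x, y) rep(TRUE, length(x)))
    ref <- spot_spp(ref_pts$x, ref_pts$y,
                    pmax(stats::rnorm(ref_n, mean_ref, sdev), 0), w, check = FALSE)
    if (case == 2) {
      n <- stats::rpois(1, truth$lambda_bg * w$area)
      pts <- sample_region_points(n, w, function(x, y) rep(TRUE, length(x)))
      test <- spot_spp(pts$x, pts$y, pmax(stats::rnorm(n, mean_test, sdev), 0),
                       w, check = FALSE)
      return(list(test = test, ref = ref, truth = NULL))
    }
    n_high <- stats::rpois(1, truth$lambda_high * truth$area_high)
    n_bg <- stats::rpois(1, truth$lambda_bg * (w$area - truth$area_high))
    hi <- sample_region_points(n_high, w, truth$in_high)
    bg <- sample_region_points(n_bg, w, function(x, y) !truth$in_high(x, y))
    marks <- if (case == 1) {
      c(pmax(stats::rnorm(n_high, mean_test, sdev), 0),
        pmax(stats::rnorm(n_bg, mean_ref, sdev), 0))
    } else {
      pmax(stats::rnorm(n_high + n_bg, mean_ref, sdev), 0)
    }
    test <- spot_spp(c(hi$x, bg$x), c(hi$y, bg$y), marks, w, check = FALSE)
    list(test = test, ref = ref, truth = truth)
  })
}
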