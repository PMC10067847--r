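# fixtures built in code; no binary files shipped

# 4-pixel, 3-peak matrix with integer intensities (exact under float32)
make_test_pm <- function() {
  peak_matrix(
    coords = data.frame(x = c(0L, 1L, 0L, 1L), y = c(0L, 0L, 1L, 1L)),
    mz = c(100.1, 200.2, 300.3),
    values = matrix(c(1, 0, 3,
                      0, 5, 0,
                      7, 8, 9,
                      2, 0, 4), nrow = 4, byrow = TRUE),
    pixel_size_um = 50, polarity = "positive"
  )
}

# profile spectrum of Gaussian peaks with FWHM following a * m/z^2
make_profile_fixture <- function(a = 3e-8, n_peaks = 60, seed = 42,
                                 mz_range = c(100, 1000), noise_sd = 0.002) {
  set.seed(seed)
  centers <- sort(runif(n_peaks, mz_range[1], mz_range[2]))
  # keep peaks well separated so flank interpolation is clean
  centers <- centers[c(TRUE, diff(centers) > 2)]
  grid <- numeric(0); intensity <- numeric(0)
  for (m in centers) {
    fwhm <- a * m^2
    sg <- fwhm / (2 * sqrt(2 * log(2)))
    x <- seq(m - 6 * sg, m + 6 * sg, length.out = 121)
    grid <- c(grid, x)
    intensity <- c(intensity, 1000 * exp(-(x - m)^2 / (2 * sg^2)))
  }
  o <- order(grid)
  intensity <- pmax(intensity[o] * (1 + rnorm(length(o), 0, noise_sd)), 0)
  profile_spectrum(grid[o], intensity)
}

# the reference ring simulation used throughout (outer 30 / inner 20,
# densities 0.4 / 0.3, mean intensity ratio 2.3)
ring_fixture <- function(seed = 11) {
  gt <- ground_truth_pattern("ring")
  list(truth = gt, sim = simulate_pattern(gt, seed = seed))
}

# small uniform pattern for fast KDE/CSR checks
small_uniform_spp <- function(n = 30, side = 20, seed = 3) {
  set.seed(seed)
  spot_spp(runif(n, 0, side), runif(n, 0, side), runif(n, 1, 5),
           square_window(side), check = FALSE)
}

# polygon area by the shoelace formula
shoelace_area <- function(poly) {
  x <- poly$x; y <- poly$y
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
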