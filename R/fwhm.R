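#' Convert a peak FWHM to the Gaussian envelope standard deviation
#'
#' For a Gaussian peak shape, FWHM = \eqn{2\sqrt{2\ln 2}\,\sigma_G}; this
#' returns \eqn{\sigma_G =} `fwhm` \eqn{/ 2\sqrt{2\ln 2}}.
#'
#' @param fwhm full width at half maximum (Da), positive.
#' @return \eqn{\sigma_G} in Da.
#' @export
sigma_from_fwhm <- function(fwhm) {
  if (any(!is.finite(fwhm)) || any(fwhm <= 0)) stop("'fwhm' must be positive")
  fwhm / FWHM_SIGMA_FACTOR
}

#' Measure per-peak FWHM values from a profile spectrum
#'
#' Detects local maxima above the noise level (signal-to-noise ratio
#' `snr_min`, noise estimated as the median absolute deviation of the
#' intensities, scaled to be consistent with a normal distribution) and
#' measures each peak's FWHM by linear interpolation of the half-maximum
#' crossings on both flanks. Peaks whose flanks do not cross half maximum
#' before rising again (overlapping neighbors) are skipped.
#'
#' @param sp a [profile_spectrum()].
#' @param snr_min minimal signal-to-noise ratio of accepted apexes
#'   (default 3).
#' @return list with numeric vectors `mz` (apex positions) and `fwhm`.
#' @export
extract_fwhm_points <- function(sp, snr_min = 3) {
  stopifnot(inherits(sp, "profile_spectrum"))
  y <- sp$intensity; x <- sp$mz
  n <- length(y)
  if (n < 5) stop("profile spectrum too short")
  noise <- stats::mad(y)
  if (noise == 0) noise <- stats::sd(y)
  if (!is.finite(noise) || noise == 0) {
    stop("no qualifying peaks found; supply a different profile spectrum")
  }
  apex <- which(diff(sign(diff(y))) == -2) + 1L
  apex <- apex[y[apex] >= snr_min * noise]
  out_mz <- numeric(0); out_fwhm <- numeric(0)
  for (p in apex) {
    half <- y[p] / 2
    # left flank: walk down until we cross half max; abort if we rise first
    li <- p; ok_l <- FALSE
    while (li > 1) {
      if (y[li - 1] > y[li]) break
      li <- li - 1L
      if (y[li] <= half) { ok_l <- TRUE; break }
    }
    ri <- p; ok_r <- FALSE
    while (ri < n) {
      if (y[ri + 1] > y[ri]) break
      ri <- ri + 1L
      if (y[ri] <= half) { ok_r <- TRUE; break }
    }
    if (!ok_l || !ok_r) next
    xl <- x[li] + (half - y[li]) / (y[li + 1] - y[li]) * (x[li + 1] - x[li])
    xr <- x[ri - 1] + (half - y[ri - 1]) / (y[ri] - y[ri - 1]) * (x[ri] - x[ri - 1])
    out_mz <- c(out_mz, x[p])
    out_fwhm <- c(out_fwhm, xr - xl)
  }
  if (length(out_mz) == 0) {
    stop("no qualifying peaks found; supply a different profile spectrum")
  }
  list(mz = out_mz, fwhm = out_fwhm)
}

#' Fit a smooth FWHM(m/z) curve by local regression
#'
#' Locally estimated scatterplot smoothing (LOESS) of measured per-peak
#' FWHM values against m/z, yielding a positive continuous estimate of the
#' instrument peak width at any m/z in the trained range. Evaluation beyond
#' the trained range clamps to the boundary value with a warning.
#'
#' @param mz,fwhm training points from [extract_fwhm_points()]; at least 10.
#' @param span LOESS span (fraction of points in each local fit).
#' @param degree degree of the local polynomials.
#' @param snr_min recorded extraction threshold (metadata only).
#' @return object of class `fwhm_curve`; evaluate it with [eval_fwhm()].
#' @export
fit_fwhm_curve <- function(mz, fwhm, span = 0.5, degree = 2, snr_min = 3) {
  mz <- as.numeric(mz); fwhm <- as.numeric(fwhm)
  if (length(mz) != length(fwhm)) stop("'mz' and 'fwhm' lengths differ")
  if (length(mz) < 10) stop("at least 10 (m/z, FWHM) points are required")
  if (any(fwhm <= 0)) stop("FWHM values must be positive")
  fit <- stats::loess(fwhm ~ mz, data = data.frame(mz = mz, fwhm = fwhm),
                      span = span, degree = degree,
                      control = stats::loess.control(surface = "direct"))
  structure(list(train_mz = mz, train_fwhm = fwhm, span = span,
                 degree = degree, snr_min = snr_min,
                 range = range(mz), fit = fit),
            class = "fwhm_curve")
}

#' Evaluate a fitted FWHM curve
#'
#' @param curve a [fit_fwhm_curve()] result.
#' @param mz m/z values (Da) at which to estimate the FWHM.
#' @return positive FWHM estimates (Da); queries outside the trained range
#'   are clamped to the range boundary with a warning.
#' @export
eval_fwhm <- function(curve, mz) {
  stopifnot(inherits(curve, "fwhm_curve"))
  mz <- as.numeric(mz)
  out_of_range <- mz < curve$range[1] | mz > curve$range[2]
  if (any(out_of_range)) {
    warnf("%d m/z value(s) outside the trained range [%.2f, %.2f]; clamping",
          sum(out_of_range), curve$range[1], curve$range[2])
    mz <- pmin(pmax(mz, curve$range[1]), curve$range[2])
  }
  pred <- as.numeric(stats::predict(curve$fit, newdata = data.frame(mz = mz)))
  floor_val <- min(curve$train_fwhm) * 1e-3
  if (any(pred <= 0)) {
    warnf("LOESS fit dipped non-positive at %d m/z value(s); clamping to a small positive floor",
          sum(pred <= 0))
    pred <- pmax(pred, floor_val)
  }
  pred
}

#' Serialize / restore an FWHM curve as JSON
#'
#' Stores the training points and smoothing parameters so the identical
#' curve can be refit reproducibly in a later session.
#'
#' @param curve a `fwhm_curve`.
#' @param path JSON file path.
#' @return `fwhm_curve_to_json` returns `path` invisibly;
#'   `fwhm_curve_from_json` returns the refit `fwhm_curve`.
#' @export
fwhm_curve_to_json <- function(curve, path) {
  stopifnot(inherits(curve, "fwhm_curve"))
  jsonlite::write_json(
    list(train_mz = curve$train_mz, train_fwhm = curve$train_fwhm,
         span = curve$span, degree = curve$degree, snr_min = curve$snr_min),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fwhm_curve_to_json
#' @export
fwhm_curve_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit_fwhm_curve(x$train_mz, x$train_fwhm, span = x$span,
                 degree = x$degree, snr_min = x$snr_min)
}

#' Theoretical peak width from instrument resolution models
#'
#' Closed-form peak width (mass resolution at FWHM) for the common
#' resolving-power regimes: the FTICR low-pressure limit
#' \eqn{\Delta m = 7.589\,m^2/(q B T_{FID})}, the collision-damped FTICR
#' regime \eqn{\Delta m = 2\sqrt{3}\,m^2/(q B \tau)}, and the TOF relation
#' \eqn{m/\Delta m = t/(2\Delta t)}, i.e. \eqn{\Delta m = 2 m \Delta t / t}.
#' These are intended for qualitative comparison against a measured
#' [fit_fwhm_curve()]; the measured curve is authoritative in the weighting
#' pipeline. Outputs are in whatever unit system the caller supplies
#' consistently for `m`, `q`, `B` and the time constants.
#'
#' @param m ion mass (the same unit the constants were chosen for).
#' @param params named list of model parameters: `q` (charge), `B`
#'   (magnetic field) and `T_fid` for `low_pressure`; `q`, `B`, `tau` for
#'   `damped`; `t` (time of flight) and `dt` (peak width in time) for `tof`.
#' @param regime `"low_pressure"`, `"damped"` or `"tof"`.
#' @return peak width \eqn{\Delta m} (same mass unit as `m`).
#' @export
theoretical_fwhm <- function(m, params, regime = c("low_pressure", "damped", "tof")) {
  regime <- match.arg(regime)
  need <- switch(regime,
                 low_pressure = c("q", "B", "T_fid"),
                 damped = c("q", "B", "tau"),
                 tof = c("t", "dt"))
  missing_p <- setdiff(need, names(params))
  if (length(missing_p)) {
    stopf("missing parameter '%s' for regime '%s'", missing_p[1], regime)
  }
  for (p in need) {
    if (!is.numeric(params[[p]]) || params[[p]] <= 0) {
      stopf("parameter '%s' must be positive", p)
    }
  }
  switch(regime,
         low_pressure = 7.589 * m^2 / (params$q * params$B * params$T_fid),
         damped = 2 * sqrt(3) * m^2 / (params$q * params$B * params$tau),
         tof = 2 * m * params$dt / params$t)
}
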