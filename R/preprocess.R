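#' Remove rarely occurring peaks from a peak matrix
#'
#' Drops m/z columns that are nonzero in less than `min_pixel_frac` of the
#' pixels, limiting the influence of spurious random peaks. The boundary is
#' strict removal below the threshold: a column present in exactly
#' `min_pixel_frac` of pixels is kept.
#'
#' @param pm a [peak_matrix()].
#' @param min_pixel_frac minimal fraction of pixels a peak must occur in
#'   (default 0.01, i.e. 1%).
#' @return a filtered [peak_matrix()] (possibly with zero columns).
#' @export
filter_rare_peaks <- function(pm, min_pixel_frac = 0.01) {
  stopifnot(inherits(pm, "msi_peaks"))
  n_pix <- nrow(pm$coords)
  occ <- Matrix::colSums(pm$values > 0)
  keep <- occ >= min_pixel_frac * n_pix
  peak_matrix(pm$coords, pm$mz[keep], pm$values[, keep, drop = FALSE],
              pixel_size_um = pm$pixel_size_um, polarity = pm$polarity)
}

#' Group peak masses by iterative bisecting
#'
#' Sorts all observed peak masses into bins by recursively splitting the
#' mass vector at the largest adjacent difference until every bin satisfies
#' the relative-deviation criterion
#' \eqn{|peak_{ij} - \mu_j| / \mu_j < tolerance}, where \eqn{\mu_j} is the
#' mean mass of the bin (its center and new peak position). Ties at the
#' largest difference split at the lowest-mass occurrence, making the
#' output deterministic.
#'
#' @param masses peak masses, sorted ascending (Da).
#' @param tolerance maximal relative deviation \eqn{\Delta m / m} as a plain
#'   fraction (e.g. `12e-6` for 12 ppm).
#' @return object of class `bin_map`: list with `bin_centers` (sorted),
#'   `assignment` (bin index per input mass) and `tolerance`. Empty input
#'   yields an empty map.
#' @export
bin_peaks <- function(masses, tolerance) {
  masses <- as.numeric(masses)
  if (is.unsorted(masses)) stop("'masses' must be sorted ascending")
  if (!is.numeric(tolerance) || tolerance <= 0) stop("'tolerance' must be positive")
  n <- length(masses)
  assignment <- integer(n)
  centers <- numeric(0)
  if (n > 0) {
    # stack of [lo, hi] index ranges still to be checked
    stack <- list(c(1L, n))
    ranges <- list()
    while (length(stack) > 0) {
      rg <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      lo <- rg[1]; hi <- rg[2]
      seg <- masses[lo:hi]
      mu <- mean(seg)
      if (all(abs(seg - mu) / mu < tolerance)) {
        ranges[[length(ranges) + 1L]] <- rg
      } else {
        gaps <- diff(seg)
        cut <- which.max(gaps)  # first occurrence of the maximal gap
        stack[[length(stack) + 1L]] <- c(lo + cut, hi)
        stack[[length(stack) + 1L]] <- c(lo, lo + cut - 1L)
      }
    }
    ranges <- ranges[order(vapply(ranges, `[`, integer(1), 1))]
    for (b in seq_along(ranges)) {
      lo <- ranges[[b]][1]; hi <- ranges[[b]][2]
      assignment[lo:hi] <- b
      centers[b] <- mean(masses[lo:hi])
    }
  }
  structure(list(bin_centers = centers, assignment = assignment,
                 tolerance = tolerance),
            class = "bin_map")
}

#' Export a bin map as a two-column audit CSV
#'
#' @param bm a [bin_peaks()] result.
#' @param path CSV output path; columns `bin_center`, `member_count`.
#' @return `path`, invisibly.
#' @export
export_binmap_csv <- function(bm, path) {
  stopifnot(inherits(bm, "bin_map"))
  counts <- tabulate(bm$assignment, nbins = length(bm$bin_centers))
  utils::write.csv(data.frame(bin_center = bm$bin_centers,
                              member_count = counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' Per-pixel intensity normalization
#'
#' `TIC` divides each pixel's intensities by their sum (total ion count);
#' `RMS` divides by the root of the mean squared intensity of that pixel;
#' `none` is the identity. All-zero pixels are left unchanged with a
#' warning.
#'
#' @param pm a [peak_matrix()].
#' @param method `"none"`, `"TIC"` or `"RMS"` (case-insensitive).
#' @return the normalized [peak_matrix()].
#' @export
normalize_pixels <- function(pm, method = c("none", "TIC", "RMS")) {
  stopifnot(inherits(pm, "msi_peaks"))
  method <- toupper(method[1])
  if (!method %in% c("NONE", "TIC", "RMS")) stopf("unknown normalization method '%s'", method)
  if (method == "NONE") return(pm)
  vals <- pm$values
  denom <- if (method == "TIC") {
    Matrix::rowSums(vals)
  } else {
    sqrt(Matrix::rowMeans(vals^2))
  }
  zero <- denom == 0
  if (any(zero)) {
    warnf("%d all-zero pixel(s) left unchanged by %s normalization", sum(zero), method)
    denom[zero] <- 1
  }
  peak_matrix(pm$coords, pm$mz, Matrix::Diagonal(x = 1 / denom) %*% vals,
              pixel_size_um = pm$pixel_size_um, polarity = pm$polarity)
}
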