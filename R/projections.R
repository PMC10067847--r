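#' z-score standardize the marks of a point pattern
#'
#' Subtracts the mark mean and divides by the sample standard deviation
#' (n-1 denominator), equalizing offset and variance between metabolites
#' with different intensity ranges and ionization efficiencies before they
#' are projected together.
#'
#' @param spp a [spot_spp()] with at least 2 points and nonzero mark
#'   variance.
#' @return a [spot_spp()] with standardized marks (mean 0, sd 1).
#' @export
zscore_standardize <- function(spp) {
  stopifnot(inherits(spp, "spot_spp"))
  if (spp$n < 2) stop("need at least 2 points to standardize")
  s <- stats::sd(spp$marks)
  if (!is.finite(s) || s == 0) stop("zero mark variance; cannot standardize")
  spot_spp(spp$x, spp$y, (spp$marks - mean(spp$marks)) / s, spp$window,
           check = FALSE)
}

#' Project an ensemble of metabolite point patterns onto one tissue plane
#'
#' Members sharing an identical observed m/z (duplicated database matches
#' of the same peak) contribute once: the first member in input order is
#' kept and the rest are counted in `dropped_duplicates`. Each retained
#' member is z-score standardized (members with fewer than 2 points or
#' constant marks are skipped with a warning), then all points are
#' concatenated into a single collective pattern; co-located points are
#' kept distinct, never summed.
#'
#' @param members list of members, each a list with fields `mz` (observed
#'   m/z) and `spp` (a [spot_spp()]); all windows must be identical.
#' @return object of class `ensemble_projection`: `members` (retained,
#'   standardized), `projected` (the collective [spot_spp()]),
#'   `dropped_duplicates`, `skipped` (names/indices of degenerate members)
#'   and `standardized = TRUE`.
#' @export
collective_project <- function(members) {
  if (length(members) == 0) stop("'members' is empty")
  for (m in members) {
    if (!is.list(m) || is.null(m$mz) || !inherits(m$spp, "spot_spp")) {
      stop("each member must be a list(mz =, spp =)")
    }
  }
  w <- members[[1]]$spp$window
  for (m in members) {
    if (!windows_identical(w, m$spp$window)) stop("member windows differ")
  }
  mzs <- vapply(members, function(m) m$mz, numeric(1))
  dup <- duplicated(mzs)
  dropped <- sum(dup)
  members <- members[!dup]
  kept <- list(); skipped <- integer(0)
  for (k in seq_along(members)) {
    m <- members[[k]]
    std <- try(zscore_standardize(m$spp), silent = TRUE)
    if (inherits(std, "try-error")) {
      warnf("ensemble member %d (m/z %.4f) skipped: constant marks or fewer than 2 points",
            k, m$mz)
      skipped <- c(skipped, k)
      next
    }
    kept[[length(kept) + 1L]] <- list(mz = m$mz, spp = std)
  }
  if (length(kept) == 0) stop("no usable ensemble members after standardization")
  projected <- spot_spp(
    x = unlist(lapply(kept, function(m) m$spp$x)),
    y = unlist(lapply(kept, function(m) m$spp$y)),
    marks = unlist(lapply(kept, function(m) m$spp$marks)),
    window = w, check = FALSE)
  structure(list(members = kept, projected = projected,
                 dropped_duplicates = dropped, skipped = skipped,
                 standardized = TRUE),
            class = "ensemble_projection")
}

#' Collective-projection probabilistic map (CPPM)
#'
#' Applies the identical probabilistic-mapping pipeline ([compute_mpm()])
#' to the projected collective pattern of a metabolite ensemble. Because
#' standardized marks can be negative while the weighted density requires
#' nonnegative marks, marks are shifted by the global minimum plus a small
#' epsilon before density estimation; the shift is recorded in the result
#' (`mark_shift`) and the projected pattern itself is left untouched.
#'
#' @param proj an [collective_project()] result.
#' @inheritParams compute_mpm
#' @return an `mpm_result` (with an extra `mark_shift` field).
#' @export
compute_cppm <- function(proj, alpha = 0.05, h = "auto", seed = NULL) {
  stopifnot(inherits(proj, "ensemble_projection"))
  spp <- proj$projected
  if (spp$n == 0) stop("projected ensemble pattern is empty")
  mn <- min(spp$marks)
  eps <- 1e-6 * max(diff(range(spp$marks)), 1)
  shift <- if (mn <= 0) -mn + eps else 0
  shifted <- spot_spp(spp$x, spp$y, spp$marks + shift, spp$window, check = FALSE)
  res <- compute_mpm(shifted, alpha = alpha, h = h, seed = seed)
  res$mark_shift <- shift
  res$spp <- spp
  res
}

#' Empirical-CDF tail p-values of test marks against a reference sample
#'
#' Nonparametric (distribution-free) tail probabilities from the reference
#' empirical cumulative distribution function, with the add-one estimator
#' so p-values are never zero:
#' \eqn{p_{upr}(x) = (1 + \#\{r \ge x\})/(n_{ref} + 1)} and
#' \eqn{p_{lwr}(x) = (1 + \#\{r \le x\})/(n_{ref} + 1)}.
#' Benjamini-Hochberg correction is applied separately per tail across the
#' test marks.
#'
#' @param test_marks numeric test-tissue intensities.
#' @param ref_marks numeric reference-tissue intensities (at least
#'   `min_ref` values).
#' @param min_ref minimal reference sample size (default 20).
#' @return list with `p_lwr`, `p_upr`, `p_lwr_adj`, `p_upr_adj`, each of
#'   length `length(test_marks)`.
#' @export
ecdf_tail_pvalues <- function(test_marks, ref_marks, min_ref = 20) {
  if (length(ref_marks) == 0) stop("empty reference sample")
  if (length(ref_marks) < min_ref) {
    stopf("reference sample too small (%d < %d)", length(ref_marks), min_ref)
  }
  n_ref <- length(ref_marks)
  sorted <- sort(ref_marks)
  # #{r >= x} and #{r <= x} via binary search on the sorted reference
  n_ge <- n_ref - findInterval(test_marks, sorted, left.open = TRUE)
  n_le <- findInterval(test_marks, sorted)
  p_upr <- (1 + n_ge) / (n_ref + 1)
  p_lwr <- (1 + n_le) / (n_ref + 1)
  list(p_lwr = p_lwr, p_upr = p_upr,
       p_lwr_adj = stats::p.adjust(p_lwr, method = "BH"),
       p_upr_adj = stats::p.adjust(p_upr, method = "BH"))
}

#' Cross-tissue molecular probabilistic map (CT-MPM)
#'
#' Conjunction of two null-hypothesis tests: (1) the spatial test — hotspot
#' and coldspot masks of the test tissue from its own [compute_mpm()]; and
#' (2) the intensity test — per-point eCDF tail p-values of the test marks
#' against the reference tissue's marks ([ecdf_tail_pvalues()]),
#' BH-corrected over test points. Pixels that reject both nulls (a spatial
#' hotspot pixel holding an upper-tail intensity-significant point, or the
#' coldspot/lower-tail analogue) are designated as having significant
#' cross-tissue relative spatial abundance or deficiency.
#'
#' Test and reference intensities must be comparable (same slide and/or
#' robust normalization); this is the caller's responsibility.
#'
#' @param test_spp,ref_spp marked point patterns of the test and reference
#'   tissues.
#' @inheritParams compute_mpm
#' @return object of class `ct_result`: the test-tissue `mpm`, per-point
#'   p-values `intensity`, logical matrices `combined_hotspot_mask` /
#'   `combined_coldspot_mask` (subsets of the spatial masks) and `alpha`.
#' @export
compute_ctmpm <- function(test_spp, ref_spp, alpha = 0.05, h = "auto", seed = NULL) {
  stopifnot(inherits(test_spp, "spot_spp"), inherits(ref_spp, "spot_spp"))
  warnf("cross-tissue comparison assumes comparable intensities between test and reference (same measurement or robust normalization)")
  mpm <- compute_mpm(test_spp, alpha = alpha, h = h, seed = seed)
  pv <- ecdf_tail_pvalues(test_spp$marks, ref_spp$marks)
  w <- test_spp$window
  idx <- coord_to_index(w, test_spp$x, test_spp$y)
  sig_up <- matrix(FALSE, w$ny, w$nx)
  sig_lo <- matrix(FALSE, w$ny, w$nx)
  up_pts <- pv$p_upr_adj <= alpha
  lo_pts <- pv$p_lwr_adj <= alpha
  sig_up[cbind(idx$row[up_pts], idx$col[up_pts])] <- TRUE
  sig_lo[cbind(idx$row[lo_pts], idx$col[lo_pts])] <- TRUE
  structure(list(mpm = mpm, intensity = pv,
                 combined_hotspot_mask = mpm$hotspot_mask & sig_up,
                 combined_coldspot_mask = mpm$coldspot_mask & sig_lo,
                 alpha = alpha),
            class = "ct_result")
}

#' @export
print.ct_result <- function(x, ...) {
  cat(sprintf(
    "Cross-tissue probabilistic map: %d combined hotspot pixel(s), %d combined coldspot pixel(s) (alpha = %g)\n",
    sum(x$combined_hotspot_mask), sum(x$combined_coldspot_mask), x$alpha))
  invisible(x)
}
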