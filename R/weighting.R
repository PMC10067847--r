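#' Data-dependent Gaussian mass window
#'
#' Erects the Gaussian weighting envelope for a metabolite of interest (MOI):
#' its standard deviation \eqn{\sigma_G} is derived from the FWHM of the
#' instrument's peaks at the MOI m/z (FWHM = \eqn{2\sqrt{2\ln 2}\,\sigma_G}),
#' and the effective support spans \eqn{m_{MOI} \pm 3\sigma_G}.
#'
#' @param m_moi theoretical MOI m/z (Da).
#' @param curve a [fit_fwhm_curve()] result, or a single numeric FWHM value
#'   (Da) used as a constant-resolution shortcut.
#' @return object of class `gaussian_window` with fields `m_moi`, `sigma_g`
#'   and `support` (length-2 numeric).
#' @export
make_window <- function(m_moi, curve) {
  if (!is.numeric(m_moi) || length(m_moi) != 1L || m_moi <= 0) {
    stop("'m_moi' must be a single positive m/z value")
  }
  fwhm <- if (is.numeric(curve)) curve else eval_fwhm(curve, m_moi)
  sigma_g <- sigma_from_fwhm(fwhm)
  structure(
    list(m_moi = m_moi, sigma_g = sigma_g,
         support = c(m_moi - 3 * sigma_g, m_moi + 3 * sigma_g)),
    class = "gaussian_window"
  )
}

#' Gaussian- or uniform-weighted summed intensity of peaks in a mass window
#'
#' Sums the intensities of all observed peaks falling within the window
#' support. In `gaussian` mode each peak is down-weighted by the envelope
#' value at its m/z, \eqn{w_j = \exp(-(m_j - m_{MOI})^2 / (2\sigma_G^2))}
#' (envelope scaled to \[0,1\], weight 1 at the center), so proximal
#' interfering signals contribute less the further they sit from the MOI.
#' In `uniform` mode all peaks in the support are weighted equally
#' (the traditional ion-image convention).
#'
#' @param mz,intensity observed peak positions (Da) and intensities; may be
#'   empty.
#' @param win a [make_window()] result.
#' @param mode `"gaussian"` or `"uniform"`.
#' @return a single summed intensity (0 when no peak falls in the support).
#' @export
weighted_intensity <- function(mz, intensity, win, mode = c("gaussian", "uniform")) {
  mode <- match.arg(mode)
  if (length(mz) != length(intensity)) stop("'mz' and 'intensity' lengths differ")
  keep <- mz >= win$support[1] & mz <= win$support[2]
  if (!any(keep)) return(0)
  m <- mz[keep]; i <- intensity[keep]
  if (mode == "uniform") return(sum(i))
  w <- exp(-((m - win$m_moi)^2) / (2 * win$sigma_g^2))
  sum(w * i)
}

#' Build the spatial point pattern of an MOI from a peak matrix
#'
#' Applies the Gaussian (or uniform) mass-window weighting to every pixel of
#' the peak matrix and emits one marked point per pixel with a positive
#' weighted intensity, located at the pixel center. The tissue window is the
#' union of all measured pixels, including those where the MOI was not
#' detected, so the point density \eqn{\Lambda = n/A_{tissue}} refers to the
#' full tissue area.
#'
#' @param pm a [peak_matrix()].
#' @param win a [make_window()] result.
#' @param mode weighting mode, see [weighted_intensity()].
#' @return a [spot_spp()]; empty (with a warning) when the MOI is absent
#'   everywhere.
#' @export
build_spp <- function(pm, win, mode = c("gaussian", "uniform")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pm, "msi_peaks"))
  if (nrow(pm$coords) == 0) stop("peak matrix has no pixels")
  keep <- which(pm$mz >= win$support[1] & pm$mz <= win$support[2])
  nx <- max(pm$coords$x) + 1L
  ny <- max(pm$coords$y) + 1L
  mask <- matrix(FALSE, nrow = ny, ncol = nx)
  mask[cbind(pm$coords$y + 1L, pm$coords$x + 1L)] <- TRUE
  window <- spot_window(mask)
  if (length(keep) == 0) {
    warnf("MOI m/z %.4f not observed in any pixel; returning an empty point pattern",
          win$m_moi)
    return(spot_spp(numeric(0), numeric(0), numeric(0), window))
  }
  w <- if (mode == "gaussian") {
    exp(-((pm$mz[keep] - win$m_moi)^2) / (2 * win$sigma_g^2))
  } else rep(1, length(keep))
  wi <- as.numeric(pm$values[, keep, drop = FALSE] %*% w)
  pos <- wi > 0
  if (!any(pos)) {
    warnf("MOI m/z %.4f not observed in any pixel; returning an empty point pattern",
          win$m_moi)
    return(spot_spp(numeric(0), numeric(0), numeric(0), window))
  }
  spot_spp(x = pm$coords$x[pos] + 0.5, y = pm$coords$y[pos] + 0.5,
           marks = wi[pos], window = window)
}

# ---- spatial arithmetic expressions --------------------------------------

validate_expr_ast <- function(e, allowed) {
  if (is.numeric(e) && length(e) == 1L) return(invisible(TRUE))
  if (is.name(e)) {
    nm <- as.character(e)
    if (!nm %in% allowed) stopf("unbound operand name '%s' in spatial expression", nm)
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(validate_expr_ast(e[[2]], allowed))
    if (!op %in% c("+", "-", "*", "/")) {
      stopf("operator '%s' is not allowed in spatial expressions (use +, -, *, /)", op)
    }
    for (k in seq_along(e)[-1]) validate_expr_ast(e[[k]], allowed)
    return(invisible(TRUE))
  }
  stop("invalid token in spatial expression")
}

#' Evaluate a spatial arithmetic expression over point patterns
#'
#' Converts each operand pattern to a raster on the common pixel grid and
#' evaluates the expression pixel by pixel. Only pixels where every operand
#' has a point contribute; pixels where a division by zero (absence of a
#' peak) or any other non-finite value occurs are dropped. The result is
#' converted back to a point pattern carrying the computed pixel values as
#' marks, ready for probabilistic mapping. Supports `+`, `-`, `*`, `/`,
#' parentheses and scalar constants, e.g. the adenylate energy charge
#' `"(atp + 0.5*adp)/(atp + adp + amp)"`.
#'
#' @param expr expression as a character string with named operands.
#' @param operands named list of [spot_spp()] objects with identical windows.
#' @return a [spot_spp()] on the shared window.
#' @export
eval_expression <- function(expr, operands) {
  stopifnot(is.character(expr), length(expr) == 1L)
  if (length(operands) == 0 || is.null(names(operands)) || any(names(operands) == "")) {
    stop("'operands' must be a named list of point patterns")
  }
  w <- operands[[1]]$window
  for (s in operands) {
    if (!windows_identical(w, s$window)) stop("operand windows differ")
  }
  ast <- parse(text = expr, keep.source = FALSE)[[1]]
  validate_expr_ast(ast, names(operands))
  if (grepl("/", expr, fixed = TRUE)) {
    warnf("spatial expression contains division; ratios may amplify intensity uncertainty")
  }
  env <- new.env(parent = baseenv())
  for (nm in names(operands)) {
    assign(nm, spp_to_raster(operands[[nm]])$values, envir = env)
  }
  vals <- eval(ast, envir = env)
  if (is.numeric(vals) && length(vals) == 1L) {
    vals <- matrix(vals, nrow = w$ny, ncol = w$nx)
  }
  vals[!is.finite(vals)] <- NA_real_
  raster_to_spp(spot_raster(vals, w$x0, w$y0), w)
}
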