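#' Tissue window for spatial point patterns
#'
#' The tissue region \eqn{\Phi_{tissue}} is represented as a union of unit
#' pixel squares: a logical mask over a rectangular grid. Pixel `(row i,
#' col j)` (1-based matrix indices) covers the square
#' `[x0+j-1, x0+j] x [y0+i-1, y0+i]` in continuous coordinates
#' (x = column direction, y = row direction, y increasing downward).
#' The window area is the number of `TRUE` pixels (unit pixel area).
#'
#' @param mask logical matrix (`ny x nx`); `TRUE` marks tissue pixels.
#' @param x0,y0 continuous coordinates of the top-left corner of the grid.
#' @return an object of class `spot_window` with fields `mask`, `x0`, `y0`,
#'   `nx`, `ny` and `area`.
#' @export
spot_window <- function(mask, x0 = 0, y0 = 0) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("'mask' must be a logical matrix")
  }
  structure(
    list(mask = mask, x0 = x0, y0 = y0,
         nx = ncol(mask), ny = nrow(mask), area = sum(mask)),
    class = "spot_window"
  )
}

#' Square tissue window
#'
#' Convenience constructor for an all-tissue square window of the given side
#' length, the geometry used by the synthetic ground-truth patterns.
#'
#' @param side side length in pixels (unit length = 1 pixel).
#' @return a [spot_window()].
#' @export
square_window <- function(side = 100) {
  spot_window(matrix(TRUE, nrow = side, ncol = side))
}

#' Pixel-center coordinates of a window grid
#' @keywords internal
window_centers <- function(w) {
  list(x = w$x0 + seq_len(w$nx) - 0.5,
       y = w$y0 + seq_len(w$ny) - 0.5)
}

# Map continuous coordinates to 1-based (row, col) grid indices; points on the
# far boundary are assigned to the last pixel.
coord_to_index <- function(w, x, y) {
  j <- pmin(pmax(floor(x - w$x0) + 1L, 1L), w$nx)
  i <- pmin(pmax(floor(y - w$y0) + 1L, 1L), w$ny)
  ok_x <- x >= w$x0 & x <= w$x0 + w$nx
  ok_y <- y >= w$y0 & y <= w$y0 + w$ny
  list(row = i, col = j, inside_bbox = ok_x & ok_y)
}

#' Test whether points fall inside a tissue window
#' @param w a [spot_window()].
#' @param x,y point coordinates.
#' @return logical vector.
#' @export
in_window <- function(w, x, y) {
  idx <- coord_to_index(w, x, y)
  ins <- idx$inside_bbox
  ins[ins] <- w$mask[cbind(idx$row[ins], idx$col[ins])]
  ins
}

windows_identical <- function(a, b) {
  isTRUE(all.equal(a$x0, b$x0)) && isTRUE(all.equal(a$y0, b$y0)) &&
    identical(dim(a$mask), dim(b$mask)) && identical(a$mask, b$mask)
}

#' Marked spatial point pattern
#'
#' The central container: 2-D points with nonnegative intensity marks inside
#' a tissue window. The overall spatial point density
#' \eqn{\Lambda = n / A_{tissue}} is recomputed at construction, so every
#' mutation routed through this constructor keeps it consistent.
#'
#' @param x,y point coordinates (continuous; MSI-derived patterns place
#'   points at pixel centers).
#' @param marks numeric intensity marks, same length as `x`.
#' @param window a [spot_window()]; all points must fall inside it.
#' @param check validate invariants (default `TRUE`).
#' @return object of class `spot_spp` with fields `x`, `y`, `marks`,
#'   `window`, `n` and `lambda`.
#' @export
spot_spp <- function(x, y, marks, window, check = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y); marks <- as.numeric(marks)
  if (length(x) != length(y) || length(x) != length(marks)) {
    stop("'x', 'y' and 'marks' must have equal length")
  }
  if (!inherits(window, "spot_window")) stop("'window' must be a spot_window")
  if (check && length(x) > 0) {
    ins <- in_window(window, x, y)
    if (!all(ins)) {
      stopf("%d point(s) fall outside the tissue window (first at x=%.3f, y=%.3f)",
            sum(!ins), x[which(!ins)[1]], y[which(!ins)[1]])
    }
  }
  structure(
    list(x = x, y = y, marks = marks, window = window,
         n = length(x),
         lambda = if (window$area > 0) length(x) / window$area else 0),
    class = "spot_spp"
  )
}

#' @export
print.spot_spp <- function(x, ...) {
  cat(sprintf(
    "Marked spatial point pattern: n = %d points, window %d x %d px (area %d), lambda = %.4g\n",
    x$n, x$window$nx, x$window$ny, x$window$area, x$lambda))
  if (x$n > 0) {
    cat(sprintf("  marks: min %.4g, median %.4g, max %.4g\n",
                min(x$marks), stats::median(x$marks), max(x$marks)))
  }
  invisible(x)
}

#' Raster image on a window grid
#'
#' A pixel-based image aligned with a window grid; `NA` encodes pixels that
#' carry no value (outside the tissue or without a detected point).
#'
#' @param values numeric matrix (`ny x nx`).
#' @param x0,y0 grid origin, as in [spot_window()].
#' @return object of class `spot_raster`.
#' @export
spot_raster <- function(values, x0 = 0, y0 = 0) {
  if (!is.matrix(values)) stop("'values' must be a matrix")
  structure(list(values = values, x0 = x0, y0 = y0), class = "spot_raster")
}

#' Convert a grid-aligned point pattern to a raster image
#'
#' Each pixel receives the mark of the point at its center; pixels without a
#' point are `NA`. Marks of co-located points (same pixel) are summed. By
#' default points must sit exactly on pixel centers (true for MSI-derived
#' patterns); `nearest = TRUE` snaps off-grid points (e.g. from simulations)
#' to the nearest pixel instead of erroring.
#'
#' @param spp a [spot_spp()].
#' @param nearest snap off-grid points to the nearest pixel center.
#' @return a [spot_raster()] on the window grid.
#' @export
spp_to_raster <- function(spp, nearest = FALSE) {
  w <- spp$window
  if (spp$n > 0 && !nearest) {
    fx <- abs((spp$x - w$x0) - (floor(spp$x - w$x0) + 0.5))
    fy <- abs((spp$y - w$y0) - (floor(spp$y - w$y0) + 0.5))
    if (any(fx > 1e-8 | fy > 1e-8)) {
      stop("point pattern is not grid-aligned; use nearest = TRUE to rasterize by nearest pixel")
    }
  }
  vals <- matrix(NA_real_, nrow = w$ny, ncol = w$nx)
  if (spp$n > 0) {
    idx <- coord_to_index(w, spp$x, spp$y)
    lin <- (idx$col - 1L) * w$ny + idx$row
    agg <- rowsum(spp$marks, lin)
    vals[as.integer(rownames(agg))] <- agg[, 1]
  }
  spot_raster(vals, w$x0, w$y0)
}

#' Convert a raster image back to a point pattern
#'
#' Emits one point per finite pixel, located at the pixel center with the
#' pixel value as its mark; non-finite pixels are dropped. The inverse of
#' [spp_to_raster()] on grid-aligned patterns.
#'
#' @param img a [spot_raster()].
#' @param window the tissue window of the resulting pattern.
#' @return a [spot_spp()].
#' @export
raster_to_spp <- function(img, window) {
  vals <- img$values
  keep <- which(is.finite(vals))
  i <- ((keep - 1L) %% nrow(vals)) + 1L
  j <- ((keep - 1L) %/% nrow(vals)) + 1L
  spot_spp(x = img$x0 + j - 0.5, y = img$y0 + i - 0.5,
           marks = vals[keep], window = window)
}
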