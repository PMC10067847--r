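#' Run the probabilistic-mapping workflow end to end and export results
#'
#' Thin orchestration over the package's building blocks: reads a
#' centroided imzML dataset and a profile spectrum, fits the FWHM curve,
#' filters rare peaks, normalizes, erects the Gaussian mass window at the
#' requested MOI m/z, builds the point pattern, computes the probabilistic
#' map, and writes all exports plus a reproducibility manifest into
#' `out_dir`.
#'
#' @param imzml path of the centroided imzML file.
#' @param profile_csv path of the m/z-intensity profile spectrum CSV
#'   (required for the FWHM model).
#' @param mz MOI m/z (Da).
#' @param out_dir output directory (created if missing).
#' @param alpha significance level.
#' @param bandwidth KDE bandwidth in pixels or `"auto"`.
#' @param normalization `"none"`, `"TIC"` or `"RMS"`.
#' @param min_pixel_frac occurrence filter threshold.
#' @param mode weighting mode, see [weighted_intensity()].
#' @param seed RNG seed for the CSR model.
#' @return the `mpm_result`, invisibly; side effect: files in `out_dir`.
#' @export
run_mpm <- function(imzml, profile_csv, mz, out_dir,
                    alpha = 0.05, bandwidth = "auto",
                    normalization = "none", min_pixel_frac = 0.01,
                    mode = "gaussian", seed = 1) {
  if (is.null(profile_csv) || !file.exists(profile_csv)) {
    stop("FWHM model requires a profile spectrum (profile_csv missing)")
  }
  pm <- read_imzml(imzml)
  pm <- filter_rare_peaks(pm, min_pixel_frac)
  pm <- normalize_pixels(pm, normalization)
  sp <- read_profile_csv(profile_csv)
  pts <- extract_fwhm_points(sp)
  curve <- fit_fwhm_curve(pts$mz, pts$fwhm)
  win <- make_window(mz, curve)
  spp <- build_spp(pm, win, mode = mode)
  res <- compute_mpm(spp, alpha = alpha, h = bandwidth, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  export_mpm(res, out_dir)
  manifest <- list(
    inputs = list(imzml = normalizePath(imzml),
                  imzml_md5 = unname(tools::md5sum(imzml)),
                  profile_csv = normalizePath(profile_csv),
                  profile_md5 = unname(tools::md5sum(profile_csv))),
    parameters = list(mz = mz, alpha = alpha,
                      bandwidth = res$bandwidth, seed = seed,
                      normalization = normalization,
                      min_pixel_frac = min_pixel_frac, mode = mode,
                      fwhm_at_moi = eval_fwhm(curve, mz),
                      sigma_g = win$sigma_g))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

write_grid_txt <- function(raster, path) {
  utils::write.table(raster$values, path, row.names = FALSE, col.names = FALSE)
}

#' Export a probabilistic map to disk
#'
#' Writes the density and corrected p-value rasters as whitespace-delimited
#' text grids, a JSON sidecar (grid dimensions, bandwidth, alpha, seed,
#' null moments), the contour polygons as GeoJSON in pixel coordinates,
#' and a rendered overlay PNG.
#'
#' @param res an `mpm_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_mpm <- function(res, dir) {
  stopifnot(inherits(res, "mpm_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_grid_txt(res$density$raster, file.path(dir, "density.txt"))
  write_grid_txt(res$pvals$p_upr_adj, file.path(dir, "p_upper_adj.txt"))
  write_grid_txt(res$pvals$p_lwr_adj, file.path(dir, "p_lower_adj.txt"))
  jsonlite::write_json(
    list(ny = nrow(res$density$raster$values),
         nx = ncol(res$density$raster$values),
         bandwidth = res$bandwidth, alpha = res$alpha,
         seed = res$seed, mu_csr = res$pvals$mu_csr,
         sigma_csr = res$pvals$sigma_csr,
         legend = list(hotspot = "red/white contours",
                       coldspot = "blue/white contours")),
    file.path(dir, "sidecar.json"), auto_unbox = TRUE, digits = NA)
  geo <- list(type = "FeatureCollection", features = c(
    lapply(res$hotspots, function(p) contour_feature(p, "hotspot")),
    lapply(res$coldspots, function(p) contour_feature(p, "coldspot"))))
  jsonlite::write_json(geo, file.path(dir, "contours.geojson"),
                       auto_unbox = TRUE, digits = NA)
  render_map(res, file.path(dir, "map.png"))
  invisible(dir)
}

contour_feature <- function(poly, kind) {
  list(type = "Feature",
       properties = list(kind = kind),
       geometry = list(type = "Polygon",
                       coordinates = list(Map(c, poly$x, poly$y))))
}

# boundary pixels of a logical mask (mask minus its 4-neighborhood erosion)
mask_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  core <- pad[2:(nr + 1), 2:(nc + 1)] &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  mask & !core
}

#' Render a probabilistic map as a PNG overlay
#'
#' Density image in an inferno-like palette with hotspot boundaries drawn
#' in red/white and coldspot boundaries in blue/white; written directly as
#' a PNG raster (no graphics device needed).
#'
#' @param res an `mpm_result`.
#' @param out PNG output path.
#' @return `out`, invisibly.
#' @export
render_map <- function(res, out) {
  stopifnot(inherits(res, "mpm_result"))
  v <- res$density$raster$values
  fin <- is.finite(v)
  rng <- range(v[fin])
  scaled <- matrix(0, nrow(v), ncol(v))
  if (diff(rng) > 0) scaled[fin] <- (v[fin] - rng[1]) / diff(rng)
  ramp <- grDevices::colorRamp(c("#000004", "#56106E", "#BB3754", "#F98C0A", "#FCFFA4"))
  rgbv <- ramp(as.vector(scaled)) / 255
  img <- array(0, dim = c(nrow(v), ncol(v), 3))
  img[, , 1] <- matrix(rgbv[, 1], nrow(v))
  img[, , 2] <- matrix(rgbv[, 2], nrow(v))
  img[, , 3] <- matrix(rgbv[, 3], nrow(v))
  for (ch in 1:3) { plane <- img[, , ch]; plane[!fin] <- 0.15; img[, , ch] <- plane }
  paint <- function(mask, rgb_col) {
    b <- mask_boundary(mask)
    for (ch in 1:3) { plane <- img[, , ch]; plane[b] <- rgb_col[ch]; img[, , ch] <<- plane }
  }
  if (sum(res$hotspot_mask) > 0) paint(res$hotspot_mask, c(1, 0.2, 0.2))
  if (sum(res$coldspot_mask) > 0) paint(res$coldspot_mask, c(0.25, 0.45, 1))
  png::writePNG(img, out)
  invisible(out)
}

#' Write a point pattern as a CSV of x, y, mark
#'
#' @param spp a [spot_spp()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
spp_to_csv <- function(spp, path) {
  utils::write.csv(data.frame(x = spp$x, y = spp$y, mark = spp$marks),
                   path, row.names = FALSE)
  invisible(path)
}
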