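#' Sparse peak matrix of a centroided MSI dataset
#'
#' Pixels x binned-m/z intensity table with integer pixel grid coordinates
#' (0-based, x = column, y = row, y increasing downward). Intensities are
#' stored in sparse-matrix representation.
#'
#' @param coords data frame with integer columns `x`, `y`; no duplicates.
#' @param mz strictly increasing numeric m/z axis (Da).
#' @param values numeric or sparse matrix, `nrow(coords)` x `length(mz)`,
#'   nonnegative.
#' @param pixel_size_um physical pixel pitch in micrometers.
#' @param polarity `"positive"` or `"negative"`.
#' @return object of class `msi_peaks`.
#' @export
peak_matrix <- function(coords, mz, values, pixel_size_um = 50,
                        polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  coords <- as.data.frame(coords)
  if (!all(c("x", "y") %in% names(coords))) stop("'coords' needs columns x and y")
  coords$x <- as.integer(coords$x); coords$y <- as.integer(coords$y)
  if (any(coords$x < 0 | coords$y < 0)) stop("pixel coordinates must be >= 0 (0-based)")
  dup <- duplicated(coords[c("x", "y")])
  if (any(dup)) {
    d <- coords[which(dup)[1], ]
    stopf("duplicate pixel coordinate (x=%d, y=%d)", d$x, d$y)
  }
  mz <- as.numeric(mz)
  if (length(mz) > 1 && any(diff(mz) <= 0)) stop("'mz' axis must be strictly increasing")
  values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (nrow(values) != nrow(coords) || ncol(values) != length(mz)) {
    stop("'values' dimensions must match pixels x mz axis")
  }
  if (length(values@x) && min(values@x) < 0) stop("intensities must be nonnegative")
  structure(list(coords = coords[c("x", "y")], mz = mz, values = values,
                 pixel_size_um = pixel_size_um, polarity = polarity),
            class = "msi_peaks")
}

#' @export
print.msi_peaks <- function(x, ...) {
  cat(sprintf("Centroided MSI peak matrix: %d pixels x %d m/z bins (%s mode, %g um pitch)\n",
              nrow(x$coords), length(x$mz), x$polarity, x$pixel_size_um))
  if (length(x$mz)) cat(sprintf("  m/z range %.4f - %.4f\n", min(x$mz), max(x$mz)))
  invisible(x)
}

#' Single-pixel full profile spectrum
#'
#' @param mz strictly increasing m/z values (Da); unsorted input is sorted
#'   with a warning.
#' @param intensity nonnegative intensities, same length.
#' @param source_pixel optional `(x, y)` pixel index of origin.
#' @return object of class `profile_spectrum`.
#' @export
profile_spectrum <- function(mz, intensity, source_pixel = NULL) {
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) stop("'mz' and 'intensity' lengths differ")
  neg <- which(intensity < 0)
  if (length(neg)) stopf("negative intensity at row %d", neg[1])
  if (is.unsorted(mz, strictly = TRUE)) {
    warnf("m/z values not strictly increasing; sorting")
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    if (any(diff(mz) == 0)) stop("duplicate m/z values in profile spectrum")
  }
  structure(list(mz = mz, intensity = intensity, source_pixel = source_pixel),
            class = "profile_spectrum")
}

# ---- imzML ----------------------------------------------------------------

IMZML_UUID <- "12345678-9abc-def0-1234-56789abcdef0"

uuid_bytes <- function(uuid) {
  hex <- gsub("-", "", uuid)
  as.raw(strtoi(substring(hex, seq(1, 31, 2), seq(2, 32, 2)), 16L))
}

#' Write a peak matrix as a processed (centroided) imzML/ibd pair
#'
#' Emits the processed-mode imzML dialect: per-spectrum centroided peak
#' lists with external binary arrays in the ibd sidecar (m/z as 64-bit
#' floats, intensities as 32-bit floats). Pixel coordinates are converted
#' from the internal 0-based convention to the 1-based imzML convention.
#' Only nonzero peaks of each pixel are written.
#'
#' @param pm a [peak_matrix()]; may have zero pixels.
#' @param path output path of the `.imzML` file; the `.ibd` sidecar is
#'   written next to it.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(pm, path) {
  stopifnot(inherits(pm, "msi_peaks"))
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  con <- try(file(ibd_path, "wb"), silent = TRUE)
  if (inherits(con, "try-error")) stopf("cannot write ibd file '%s'", ibd_path)
  on.exit(close(con), add = TRUE)
  writeBin(uuid_bytes(IMZML_UUID), con)
  offset <- 16
  n_pix <- nrow(pm$coords)
  spectra <- character(n_pix)
  dense <- as.matrix(pm$values)
  for (s in seq_len(n_pix)) {
    nz <- which(dense[s, ] > 0)
    k <- length(nz)
    mz_len <- 8L * k; int_len <- 4L * k
    writeBin(pm$mz[nz], con, size = 8, endian = "little")
    mz_off <- offset; offset <- offset + mz_len
    writeBin(as.numeric(dense[s, nz]), con, size = 4, endian = "little")
    int_off <- offset; offset <- offset + int_len
    spectra[s] <- paste0(
      sprintf('   <spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">\n', s - 1L, s, k),
      '    <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>\n',
      '    <scanList count="1"><scan>\n',
      sprintf('     <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n', pm$coords$x[s] + 1L),
      sprintf('     <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n', pm$coords$y[s] + 1L),
      '    </scan></scanList>\n',
      '    <binaryDataArrayList count="2">\n',
      '     <binaryDataArray encodedLength="0">\n',
      '      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>\n',
      '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
      sprintf('      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>\n', mz_off),
      sprintf('      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n', k),
      sprintf('      <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n', mz_len),
      '      <binary/>\n     </binaryDataArray>\n',
      '     <binaryDataArray encodedLength="0">\n',
      '      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>\n',
      '      <cvParam cvRef="MS" accession="MS:1000521" name="32-bit float"/>\n',
      sprintf('      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>\n', int_off),
      sprintf('      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n', k),
      sprintf('      <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n', int_len),
      '      <binary/>\n     </binaryDataArray>\n',
      '    </binaryDataArrayList>\n   </spectrum>\n')
  }
  polarity_cv <- if (pm$polarity == "positive") {
    '   <cvParam cvRef="MS" accession="MS:1000130" name="positive scan"/>\n'
  } else {
    '   <cvParam cvRef="MS" accession="MS:1000129" name="negative scan"/>\n'
  }
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    ' <cvList count="2">\n',
    '  <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology"/>\n',
    '  <cv id="IMS" fullName="Imaging MS Ontology"/>\n',
    ' </cvList>\n',
    ' <fileDescription>\n  <fileContent>\n',
    '   <cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>\n',
    sprintf('   <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>\n', IMZML_UUID),
    polarity_cv,
    sprintf('   <userParam name="pixel_size_um" value="%g"/>\n', pm$pixel_size_um),
    '  </fileContent>\n </fileDescription>\n',
    sprintf(' <run id="run0">\n  <spectrumList count="%d">\n', n_pix),
    paste0(spectra, collapse = ""),
    '  </spectrumList>\n </run>\n</mzML>\n')
  ok <- try(writeLines(xml, path, sep = ""), silent = TRUE)
  if (inherits(ok, "try-error")) stopf("cannot write imzML file '%s'", path)
  invisible(path)
}

imzml_cv <- function(node, accession) {
  xml2::xml_find_first(node, sprintf(".//d1:cvParam[@accession='%s']", accession))
}

#' Read a processed (centroided) imzML/ibd pair into a peak matrix
#'
#' Supports the processed (centroided) imzML mode only; continuous-mode
#' (profile) files are rejected with an explicit error. Both 32- and 64-bit
#' float arrays are accepted. 1-based imzML pixel indices are converted to
#' the internal 0-based convention; intensities are preserved at the stored
#' binary precision. Spectra sharing a pixel coordinate raise an error.
#'
#' @param path path of the `.imzML` file; the `.ibd` sidecar must sit next
#'   to it.
#' @return a [peak_matrix()] with the union of all observed m/z values as
#'   its axis.
#' @export
read_imzml <- function(path) {
  if (!file.exists(path)) stopf("imzML file '%s' not found", path)
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd_path)) stopf("ibd sidecar '%s' not found", ibd_path)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "d1")
  find1 <- function(node, xp) xml2::xml_find_first(node, xp, ns)
  findall <- function(node, xp) xml2::xml_find_all(node, xp, ns)
  content <- find1(doc, ".//d1:fileContent")
  if (!inherits(content, "xml_missing")) {
    cont_mode <- findall(content, ".//d1:cvParam[@accession='IMS:1000030']")
    if (length(cont_mode) > 0) {
      stop("profile imzML unsupported; centroid first (file is continuous mode)")
    }
  }
  polarity <- if (length(findall(doc, ".//d1:cvParam[@accession='MS:1000129']")) > 0) {
    "negative"
  } else "positive"
  px_node <- find1(doc, ".//d1:userParam[@name='pixel_size_um']")
  pixel_size <- if (inherits(px_node, "xml_missing")) 50 else
    as.numeric(xml2::xml_attr(px_node, "value"))
  spectra <- findall(doc, ".//d1:spectrum")
  ibd <- file(ibd_path, "rb")
  on.exit(close(ibd), add = TRUE)
  read_array <- function(bda) {
    off <- as.numeric(xml2::xml_attr(find1(bda, ".//d1:cvParam[@accession='IMS:1000102']"), "value"))
    len <- as.integer(xml2::xml_attr(find1(bda, ".//d1:cvParam[@accession='IMS:1000103']"), "value"))
    size <- if (length(findall(bda, ".//d1:cvParam[@accession='MS:1000523']")) > 0) 8L else 4L
    seek(ibd, where = off, origin = "start")
    readBin(ibd, what = "double", n = len, size = size, endian = "little")
  }
  xs <- integer(0); ys <- integer(0)
  peak_mz <- vector("list", length(spectra))
  peak_int <- vector("list", length(spectra))
  for (s in seq_along(spectra)) {
    sp <- spectra[[s]]
    x <- as.integer(xml2::xml_attr(find1(sp, ".//d1:cvParam[@accession='IMS:1000050']"), "value"))
    y <- as.integer(xml2::xml_attr(find1(sp, ".//d1:cvParam[@accession='IMS:1000051']"), "value"))
    xs[s] <- x - 1L; ys[s] <- y - 1L
    bdas <- findall(sp, ".//d1:binaryDataArray")
    for (bda in bdas) {
      if (length(findall(bda, ".//d1:cvParam[@accession='MS:1000514']")) > 0) {
        peak_mz[[s]] <- read_array(bda)
      } else if (length(findall(bda, ".//d1:cvParam[@accession='MS:1000515']")) > 0) {
        peak_int[[s]] <- read_array(bda)
      }
    }
  }
  dup <- duplicated(data.frame(xs, ys))
  if (any(dup)) {
    k <- which(dup)[1]
    stopf("duplicate pixel coordinate (x=%d, y=%d) in imzML file", xs[k], ys[k])
  }
  axis <- sort(unique(unlist(peak_mz)))
  n_pix <- length(spectra)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (s in seq_len(n_pix)) {
    if (length(peak_mz[[s]]) == 0) next
    jj <- c(jj, match(peak_mz[[s]], axis))
    ii <- c(ii, rep.int(s, length(peak_mz[[s]])))
    vv <- c(vv, peak_int[[s]])
  }
  values <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                                 dims = c(n_pix, length(axis)))
  peak_matrix(data.frame(x = xs, y = ys), axis, values,
              pixel_size_um = pixel_size, polarity = polarity)
}

# ---- CSV inputs -----------------------------------------------------------

#' Read a two-column m/z-intensity profile spectrum CSV
#'
#' Accepts the flexImaging-style export: two numeric columns (m/z,
#' intensity) with an optional header line. Rows are sorted by m/z if
#' needed (with a warning); negative intensities are rejected.
#'
#' @param path CSV path.
#' @return a [profile_spectrum()].
#' @export
read_profile_csv <- function(path) {
  if (!file.exists(path)) stopf("profile CSV '%s' not found", path)
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[-+0-9.eE]+\\s*[,;\\t]", first)
  df <- utils::read.csv(path, header = has_header, strip.white = TRUE)
  if (ncol(df) < 2) stop("profile CSV must have at least two columns (m/z, intensity)")
  mz <- suppressWarnings(as.numeric(df[[1]]))
  intensity <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(mz) || anyNA(intensity)) {
    stopf("non-numeric value in profile CSV at row %d",
          which(is.na(mz) | is.na(intensity))[1])
  }
  profile_spectrum(mz, intensity)
}

#' Read a METASPACE-style metabolite annotation export
#'
#' Parses the annotation CSV (comment lines starting with `#` are skipped)
#' and retains entries at or below the requested FDR level. Column names
#' follow the current METASPACE export header and can be remapped through
#' `schema` to absorb export-format drift.
#'
#' @param path CSV path.
#' @param fdr_max maximal FDR level to retain (e.g. 0.2).
#' @param schema named character vector mapping the internal fields
#'   `formula`, `adduct`, `mz`, `fdr` (and optionally `moi_name`) to the
#'   file's column names.
#' @return object of class `annotation_set`: a data frame with columns
#'   `moi_name`, `formula`, `adduct`, `theoretical_mz`, `fdr_level`, plus an
#'   attribute `n_dropped` counting entries above `fdr_max`.
#' @export
read_annotations <- function(path, fdr_max = 0.2,
                             schema = c(formula = "formula", adduct = "adduct",
                                        mz = "mz", fdr = "fdr",
                                        moi_name = "moleculeNames")) {
  if (!file.exists(path)) stopf("annotation CSV '%s' not found", path)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        strip.white = TRUE)
  for (field in c("formula", "adduct", "mz", "fdr")) {
    if (!schema[[field]] %in% names(df)) {
      stopf("annotation CSV is missing required column '%s'", schema[[field]])
    }
  }
  moi_col <- if ("moi_name" %in% names(schema) && schema[["moi_name"]] %in% names(df)) {
    as.character(df[[schema[["moi_name"]]]])
  } else {
    paste0(df[[schema[["formula"]]]], df[[schema[["adduct"]]]])
  }
  out <- data.frame(
    moi_name = moi_col,
    formula = as.character(df[[schema[["formula"]]]]),
    adduct = as.character(df[[schema[["adduct"]]]]),
    theoretical_mz = as.numeric(df[[schema[["mz"]]]]),
    fdr_level = as.numeric(df[[schema[["fdr"]]]]),
    stringsAsFactors = FALSE
  )
  if (any(out$theoretical_mz <= 0, na.rm = TRUE)) stop("non-positive m/z in annotation CSV")
  keep <- out$fdr_level <= fdr_max
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(sprintf("read_annotations: dropped %d entries with FDR > %g", dropped, fdr_max))
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_dropped = dropped, class = c("annotation_set", "data.frame"))
}
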