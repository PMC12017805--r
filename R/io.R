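## Readers and writers. Image stacks and float parameter maps travel
## as NIfTI volumes (lossless float64, multi-frame) with a YAML
## sidecar carrying wavelengths/times/calibration metadata; masks are
## additionally accepted as PNG or TIFF (8-bit 0/255 or 0/1 dialects
## are normalized). Tables are CSV, summaries JSON.

.sidecarPath <- function(path) {
  base <- sub("\\.nii\\.gz$|\\.[A-Za-z0-9]+$", "", path)
  paste0(base, ".yaml")
}

#' Write / read a float image stack
#'
#' Stacks (height x width x frames) and single maps round-trip
#' bit-exactly through NIfTI (float64); metadata round-trips through
#' the YAML sidecar written next to the image.
#'
#' @param x numeric array (height x width x frames) or matrix.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param metadata named list written to the YAML sidecar
#'   (`<path>.yaml`); omitted when empty.
#' @return `path`, invisibly.
#' @export
writeImageStack <- function(x, path, metadata = list()) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  RNifti::writeNifti(RNifti::asNifti(x, datatype = "double"), path,
                     datatype = "double")
  if (length(metadata))
    yaml::write_yaml(metadata, .sidecarPath(path))
  invisible(path)
}

#' @rdname writeImageStack
#' @return `readImageStack()`: the numeric array, with the sidecar
#'   list (if present) attached as attribute `"metadata"`.
#' @export
readImageStack <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  nii <- RNifti::readNifti(path)
  x <- array(as.numeric(nii), dim(nii))
  sc <- .sidecarPath(path)
  if (file.exists(sc)) attr(x, "metadata") <- yaml::read_yaml(sc)
  x
}

.requireKeys <- function(meta, keys, where) {
  miss <- setdiff(keys, names(meta))
  if (length(miss))
    stop(sprintf("sidecar for %s is missing key(s): %s", where,
                 paste(miss, collapse = ", ")))
}

#' Write / read a multispectral stack with its sidecar
#'
#' The sidecar carries `wavelengths` (nm), `cal_intensity` (counts per
#' wavelength) and `standard_reflectance`.
#'
#' @param stack a [SpectralStack-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path` invisibly; `readSpectralStack()` returns the
#'   [SpectralStack-class].
#' @export
writeSpectralStack <- function(stack, path) {
  stopifnot(is(stack, "SpectralStack"))
  writeImageStack(stack@frames, path, metadata = list(
    wavelengths = stack@wavelengths,
    cal_intensity = stack@calIntensity,
    standard_reflectance = stack@standardReflectance))
}

#' @rdname writeSpectralStack
#' @export
readSpectralStack <- function(path) {
  x <- readImageStack(path)
  meta <- attr(x, "metadata")
  if (is.null(meta)) stop("no sidecar YAML found for ", path)
  .requireKeys(meta, c("wavelengths", "cal_intensity"), path)
  SpectralStack(array(x, dim(x)), unlist(meta$wavelengths),
                unlist(meta$cal_intensity),
                meta$standard_reflectance %||% 0.20)
}

#' Write / read a fluorescence series with its sidecar
#'
#' The sidecar carries `probe`, `times` (min) and the acquisition
#' metadata `gain` and `exposure`.
#'
#' @param series a [FluorSeries-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path` invisibly; `readFluorSeries()` returns the
#'   [FluorSeries-class].
#' @export
writeFluorSeries <- function(series, path) {
  stopifnot(is(series, "FluorSeries"))
  writeImageStack(series@frames, path, metadata = list(
    probe = series@probe, times = series@times,
    gain = series@gain, exposure = series@exposure))
}

#' @rdname writeFluorSeries
#' @export
readFluorSeries <- function(path) {
  x <- readImageStack(path)
  meta <- attr(x, "metadata")
  if (is.null(meta)) stop("no sidecar YAML found for ", path)
  .requireKeys(meta, c("probe", "times"), path)
  FluorSeries(meta$probe, unlist(meta$times), array(x, dim(x)),
              gain = meta$gain %||% NA_real_,
              exposure = meta$exposure %||% NA_real_)
}

#' Read a binary mask image
#'
#' Accepts PNG, TIFF or NIfTI. 8-bit masks using the 0/255 dialect are
#' normalized to 0/1 (with a message); any strictly positive value
#' counts as inside the mask.
#'
#' @param path mask image path.
#' @return Logical matrix, TRUE = masked-in (vessel) pixel.
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop("no such mask file: ", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  m <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    nii = readImageStack(path),
    stop("unsupported mask format: .", ext))
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  vals <- sort(unique(as.vector(m)))
  if (isTRUE(all.equal(vals, c(0, 1))) && ext %in% c("png", "tif", "tiff"))
    message("mask read as 0/255 8-bit dialect; normalized to 0/1")
  matrix(m > 0, nrow(m), ncol(m))
}

#' Write a binary mask as PNG
#'
#' @param mask logical or 0/1 matrix.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

#' Write a parameter map with unit metadata
#'
#' Float map as NIfTI plus a sidecar declaring the parameter name and
#' units (indicator units for hemoglobin products, fraction for StO2,
#' background-subtracted counts for endpoints); missing pixels are
#' stored as NaN.
#'
#' @param map numeric matrix.
#' @param path output path.
#' @param parameter,units strings recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
writeMap <- function(map, path, parameter = "map", units = "arbitrary") {
  writeImageStack(map, path,
                  metadata = list(parameter = parameter, units = units,
                                  missing = "NaN"))
}
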