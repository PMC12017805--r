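## Fluorescence metabolic endpoint extraction: baseline subtraction,
## integer pixel-shift co-registration, vessel exclusion, uptake
## kinetics and the 2-NBDG60 / TMRE80 endpoint maps.

#' Subtract the pre-injection baseline from a fluorescence series
#'
#' Every frame minus the t = 0 baseline frame. Negative differences
#' are clipped at zero by default (fluorescence below the
#' pre-injection baseline carries no uptake information); set
#' `clip = FALSE` to keep signed values.
#'
#' @param series a [FluorSeries-class] (baseline frame at t = 0).
#' @param clip clip negative post-subtraction values at 0?
#' @return A [FluorSeries-class] of background-subtracted frames (the
#'   baseline frame becomes the zero frame).
#' @export
subtractBackground <- function(series, clip = TRUE) {
  stopifnot(is(series, "FluorSeries"))
  if (series@times[1L] != 0)
    stop("series has no baseline frame at t = 0")
  fr <- series@frames
  base <- fr[, , 1L]
  for (i in seq_along(series@times)) {
    f <- fr[, , i] - base
    if (clip) f[f < 0] <- 0
    fr[, , i] <- f
  }
  methods::initialize(series, frames = fr)
}

#' Estimate an integer pixel shift between two images
#'
#' Exhaustive search over integer shifts in
#' `[-maxShift, maxShift]^2`, maximizing the normalized
#' cross-correlation over the overlapping region. Ties are broken by
#' the smallest shift magnitude, then row-major order. A warning is
#' issued when the best shift sits on the search-window boundary (the
#' true shift may be larger).
#'
#' @param reference,moving numeric matrices of the same shape. The
#'   returned `(dy, dx)` is the displacement of `moving` relative to
#'   `reference`: `moving[y, x] ~ reference[y - dy, x - dx]`, so
#'   translating `moving` by `-(dy, dx)` aligns it onto `reference`.
#' @param maxShift search radius in pixels, default 10.
#' @return Integer vector `c(dy = , dx = )`.
#' @examples
#' img <- matrix(rnorm(400), 20)
#' registerShift(img, img)
#' @export
registerShift <- function(reference, moving, maxShift = 10L) {
  if (!identical(dim(reference), dim(moving)))
    stop("'reference' and 'moving' must have the same shape")
  h <- nrow(reference); w <- ncol(reference)
  maxShift <- as.integer(maxShift)
  if ((h - maxShift) * (w - maxShift) < 0.25 * h * w)
    stop("overlap at maximal shift would be below 25% of the image; ",
         "reduce 'maxShift'")
  grid <- expand.grid(dx = -maxShift:maxShift, dy = -maxShift:maxShift)
  ord <- order(grid$dy^2 + grid$dx^2,
               match(grid$dy, -maxShift:maxShift),
               match(grid$dx, -maxShift:maxShift))
  best <- c(0L, 0L); bestCor <- -Inf
  for (i in ord) {
    dy <- grid$dy[i]; dx <- grid$dx[i]
    ## candidate: moving[y, x] == reference[y - dy, x - dx]
    ys <- max(1L, 1L + dy):min(h, h + dy)
    xs <- max(1L, 1L + dx):min(w, w + dx)
    a <- reference[ys - dy, xs - dx]
    b <- moving[ys, xs]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    cc <- stats::cor(as.vector(a), as.vector(b))
    if (cc > bestCor + 1e-12) {
      bestCor <- cc
      best <- c(dy, dx)
    }
  }
  if (any(abs(best) == maxShift))
    warning("best shift lies on the search-window boundary; ",
            "the true displacement may exceed maxShift")
  c(dy = best[1L], dx = best[2L])
}

#' Build the non-vessel analysis mask
#'
#' Combines the reflectance-derived vessel mask (major vessels,
#' shifted into the fluorescence frame) with the fluorescence-derived
#' vessel mask (small vessels), optionally dilates the union to absorb
#' absorption bleed at vessel edges, and complements it: the analysis
#' mask marks the non-vessel tissue pixels used for all fluorescence
#' quantification.
#'
#' @param reflectanceVesselMask logical matrix from the
#'   diffuse-reflectance image (TRUE = vessel).
#' @param fluorVesselMask logical matrix from the fluorescence image,
#'   same shape.
#' @param shift integer `c(dy, dx)`: the displacement of the
#'   reflectance image relative to the fluorescence image, as returned
#'   by `registerShift(fluorescenceFrame, reflectanceFrame)`. The
#'   reflectance mask (only) is translated by `-shift` to undo it.
#' @param dilate dilation radius (px) applied to the combined vessel
#'   mask; default 1.
#' @return Logical matrix, TRUE = analyzed (non-vessel) pixel.
#' @export
buildAnalysisMask <- function(reflectanceVesselMask, fluorVesselMask,
                              shift = c(0L, 0L), dilate = 1L) {
  r <- reflectanceVesselMask > 0
  f <- fluorVesselMask > 0
  if (!identical(dim(r), dim(f)))
    stop("vessel masks must have the same shape")
  rShifted <- shiftImage(r * 1, -shift[1L], -shift[2L], fill = 0) > 0
  vessel <- rShifted | f
  if (dilate > 0L) vessel <- dilateMask(vessel, as.integer(dilate))
  analysis <- !vessel
  if (!any(analysis))
    stop("analysis mask is empty: vessel masks cover the whole image")
  analysis
}

#' Uptake kinetic curve over the non-vessel tissue
#'
#' Mean background-subtracted intensity over the analysis-mask pixels
#' at every timepoint.
#'
#' @param series a [FluorSeries-class]; background-subtracted
#'   automatically if its baseline frame is not already zero.
#' @param analysisMask logical matrix, TRUE = analyzed pixel.
#' @return Data frame of class `kinetic_curve` with columns `time`
#'   (min), `meanIntensity`, `nPixels`.
#' @export
uptakeKinetics <- function(series, analysisMask) {
  stopifnot(is(series, "FluorSeries"))
  analysisMask <- analysisMask > 0
  if (!identical(dim(analysisMask), dim(series@frames)[1:2]))
    stop("'analysisMask' must match the frame shape")
  if (!any(analysisMask)) stop("'analysisMask' selects no pixels")
  if (any(series@frames[, , 1L] != 0))
    series <- subtractBackground(series)
  n <- sum(analysisMask)
  m <- vapply(seq_along(series@times),
              function(i) mean(series@frames[, , i][analysisMask]),
              0)
  out <- data.frame(time = series@times, meanIntensity = m, nPixels = n)
  class(out) <- c("kinetic_curve", "data.frame")
  out
}

#' Endpoint uptake map at a fixed time post-injection
#'
#' Selects the acquired frame nearest the requested endpoint time
#' (ties broken toward the earlier frame), background-subtracts it and
#' restricts it to the analysis mask. Errors when no acquired frame is
#' within `tolerance` of the requested time.
#'
#' @param series a [FluorSeries-class].
#' @param analysisMask logical matrix, TRUE = analyzed pixel.
#' @param endpointTime requested time, min; defaults to 60 for 2-NBDG
#'   and 80 for TMRE.
#' @param tolerance maximal allowed |acquired - requested| gap, min.
#' @return An [EndpointMap-class].
#' @export
endpointMap <- function(series, analysisMask, endpointTime = NULL,
                        tolerance = 5) {
  stopifnot(is(series, "FluorSeries"))
  analysisMask <- analysisMask > 0
  endpointTime <- endpointTime %||%
    if (series@probe == "NBDG") 60 else 80
  gap <- abs(series@times - endpointTime)
  i <- which(gap == min(gap))[1L]   # ties resolve to the earlier frame
  if (gap[i] > tolerance)
    stop(sprintf(
      "no acquired frame within %g min of the requested endpoint %g min",
      tolerance, endpointTime))
  if (any(series@frames[, , 1L] != 0))
    series <- subtractBackground(series)
  img <- series@frames[, , i]
  img[!analysisMask] <- NA_real_
  new("EndpointMap", probe = series@probe, endpointTime = endpointTime,
      selectedTime = series@times[i], image = img,
      analysisMask = analysisMask)
}
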