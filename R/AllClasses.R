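#' @import methods
NULL

## Central containers for the pipeline. Images are numeric matrices
## (height x width, row-major origin top-left); stacks/series are 3-D
## arrays with the spectral or temporal dimension last. Missing pixels
## are NA throughout -- never zeros.

#' Multispectral dark-field diffuse-reflectance stack
#'
#' One calibrated reflectance frame per imaging wavelength of a single
#' scene, together with the reflectance-standard calibration intensity
#' for each wavelength.
#'
#' @slot frames numeric array, height x width x n_wavelengths, intensity
#'   counts measured on tissue (\eqn{I_{tissue}}).
#' @slot wavelengths numeric, nm, strictly increasing, one per frame.
#' @slot calIntensity numeric, counts per wavelength measured on the
#'   reflectance standard (\eqn{I_{cal}}); all positive.
#' @slot standardReflectance numeric scalar, nominal reflectance of the
#'   calibration standard (default 0.20).
#'
#' @seealso [SpectralStack()], [computeAbsorbance()]
#' @export
setClass("SpectralStack",
  representation(
    frames = "array",
    wavelengths = "numeric",
    calIntensity = "numeric",
    standardReflectance = "numeric"
  )
)

setValidity("SpectralStack", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L)
    msg <- c(msg, "'frames' must be a 3-D array (height x width x wavelength)")
  else {
    if (d[3L] != length(object@wavelengths))
      msg <- c(msg, "number of frames must equal number of wavelengths")
    if (length(object@calIntensity) != length(object@wavelengths))
      msg <- c(msg, "'calIntensity' must have one entry per wavelength")
  }
  if (length(object@wavelengths) && any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "'wavelengths' must be strictly increasing")
  if (any(!is.finite(object@calIntensity)) || any(object@calIntensity <= 0))
    msg <- c(msg, "'calIntensity' must be finite and > 0")
  if (length(object@standardReflectance) != 1L ||
      !is.finite(object@standardReflectance) ||
      object@standardReflectance <= 0 || object@standardReflectance > 1)
    msg <- c(msg, "'standardReflectance' must be a single value in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a SpectralStack
#'
#' @param frames height x width x n_wavelengths array of tissue
#'   intensities (counts), or a list of matrices (one per wavelength).
#' @param wavelengths numeric vector of wavelengths in nm.
#' @param calIntensity calibration-standard intensity per wavelength
#'   (recycled if scalar).
#' @param standardReflectance nominal standard reflectance, default 0.20.
#' @return A [SpectralStack-class] object.
#' @examples
#' s <- SpectralStack(array(100, c(8, 8, 4)), c(540, 560, 580, 610), 1000)
#' dim(frames(s))
#' @export
SpectralStack <- function(frames, wavelengths, calIntensity,
                          standardReflectance = 0.20) {
  if (is.list(frames))
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dim(frames[[1L]]), length(frames)))
  calIntensity <- rep_len(as.numeric(calIntensity), length(wavelengths))
  new("SpectralStack", frames = frames,
      wavelengths = as.numeric(wavelengths),
      calIntensity = calIntensity,
      standardReflectance = standardReflectance)
}

#' Per-pixel absorbance stack
#'
#' Base-10 absorbance \eqn{A(\lambda) = \log_{10}(I_{cal}/I_{tissue})}
#' per pixel per wavelength, with a validity flag marking pixels where
#' absorbance is undefined (non-positive intensity).
#'
#' @slot A numeric array, height x width x n_wavelengths.
#' @slot wavelengths numeric, nm.
#' @slot valid logical matrix, height x width; FALSE where any
#'   wavelength is undefined.
#' @export
setClass("AbsorbanceStack",
  representation(A = "array", wavelengths = "numeric", valid = "matrix")
)

setValidity("AbsorbanceStack", function(object) {
  msg <- character()
  d <- dim(object@A)
  if (length(d) != 3L || d[3L] != length(object@wavelengths))
    msg <- c(msg, "'A' must be height x width x n_wavelengths")
  else if (!identical(dim(object@valid), d[1:2]))
    msg <- c(msg, "'valid' must match the frame shape")
  if (any(!is.finite(object@A[rep(object@valid, length(object@wavelengths))])))
    msg <- c(msg, "'A' must be finite wherever 'valid' is TRUE")
  if (length(msg)) msg else TRUE
})

#' Per-pixel chromophore fit maps
#'
#' Pixelwise non-negative least-squares fits of the modified
#' Beer-Lambert model: offset `b0`, attenuation scale `b1`, and
#' oxy-/deoxy-hemoglobin concentration-pathlength products, with the
#' per-pixel coefficient of determination and acceptance flag.
#'
#' @slot b0,b1,cHbO2,cHb numeric matrices of fitted coefficients
#'   (all non-negative; NA where the pixel was invalid).
#' @slot r2 numeric matrix, per-pixel R-squared (NA where undefined).
#' @slot accepted logical matrix, TRUE where r2 >= threshold.
#' @slot r2Threshold numeric scalar, the acceptance threshold used.
#' @export
setClass("ChromophoreMaps",
  representation(
    b0 = "matrix", b1 = "matrix", cHbO2 = "matrix", cHb = "matrix",
    r2 = "matrix", accepted = "matrix", r2Threshold = "numeric"
  )
)

setValidity("ChromophoreMaps", function(object) {
  msg <- character()
  d <- dim(object@b0)
  for (nm in c("b1", "cHbO2", "cHb", "r2", "accepted"))
    if (!identical(dim(slot(object, nm)), d))
      msg <- c(msg, sprintf("'%s' must match the shape of 'b0'", nm))
  for (nm in c("b0", "b1", "cHbO2", "cHb")) {
    v <- slot(object, nm)
    if (any(v < -1e-12, na.rm = TRUE))
      msg <- c(msg, sprintf("'%s' must be non-negative", nm))
  }
  acc <- object@accepted & !is.na(object@accepted)
  if (any(acc & (is.na(object@r2) | object@r2 < object@r2Threshold - 1e-12)))
    msg <- c(msg, "accepted pixels must satisfy r2 >= r2Threshold")
  if (length(msg)) msg else TRUE
})

#' Vascular parameter maps
#'
#' StO2 (hemoglobin oxygen saturation, fraction), THb/Hb/HbO2
#' indicators restricted to accepted vessel pixels; NA elsewhere.
#'
#' @slot StO2,THb,Hb,HbO2 numeric matrices; NA outside the vessel mask,
#'   where the fit was rejected, or (StO2 only) where THb is zero.
#' @slot vesselMask logical matrix, TRUE = vessel.
#' @export
setClass("VascularMaps",
  representation(
    StO2 = "matrix", THb = "matrix", Hb = "matrix", HbO2 = "matrix",
    vesselMask = "matrix"
  )
)

setValidity("VascularMaps", function(object) {
  msg <- character()
  d <- dim(object@StO2)
  for (nm in c("THb", "Hb", "HbO2", "vesselMask"))
    if (!identical(dim(slot(object, nm)), d))
      msg <- c(msg, sprintf("'%s' must match the shape of 'StO2'", nm))
  ok <- !is.na(object@StO2)
  if (any(object@StO2[ok] < -1e-12 | object@StO2[ok] > 1 + 1e-12))
    msg <- c(msg, "StO2 must lie in [0, 1] wherever defined")
  both <- !is.na(object@THb) & !is.na(object@Hb) & !is.na(object@HbO2)
  if (any(abs(object@THb[both] - object@Hb[both] - object@HbO2[both]) > 1e-9))
    msg <- c(msg, "THb must equal Hb + HbO2 wherever defined")
  if (length(msg)) msg else TRUE
})

#' Timestamped fluorescence image series for one metabolic probe
#'
#' @slot probe character, `"NBDG"` or `"TMRE"`.
#' @slot times numeric, minutes since this probe's injection; strictly
#'   increasing and starting at 0 (the pre-injection baseline frame).
#' @slot frames numeric array, height x width x n_times, counts.
#' @slot gain,exposure acquisition metadata (camera gain; exposure, ms).
#' @export
setClass("FluorSeries",
  representation(
    probe = "character", times = "numeric", frames = "array",
    gain = "numeric", exposure = "numeric"
  )
)

setValidity("FluorSeries", function(object) {
  msg <- character()
  if (!object@probe %in% c("NBDG", "TMRE"))
    msg <- c(msg, "'probe' must be \"NBDG\" or \"TMRE\"")
  d <- dim(object@frames)
  if (length(d) != 3L || d[3L] != length(object@times))
    msg <- c(msg, "'frames' must be height x width x n_times")
  if (length(object@times)) {
    if (object@times[1L] != 0)
      msg <- c(msg, "'times' must start at 0 (baseline frame)")
    if (any(diff(object@times) <= 0))
      msg <- c(msg, "'times' must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FluorSeries
#'
#' @param probe `"NBDG"` or `"TMRE"`.
#' @param times minutes post-injection, starting at 0.
#' @param frames height x width x n_times array, or list of matrices.
#' @param gain,exposure acquisition metadata.
#' @return A [FluorSeries-class] object.
#' @export
FluorSeries <- function(probe, times, frames, gain = NA_real_,
                        exposure = NA_real_) {
  if (is.list(frames))
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dim(frames[[1L]]), length(frames)))
  new("FluorSeries", probe = probe, times = as.numeric(times),
      frames = frames, gain = gain, exposure = exposure)
}

#' Background-subtracted endpoint uptake map
#'
#' The probe uptake image at the endpoint time (60 min for 2-NBDG,
#' 80 min for TMRE), background-subtracted and restricted to the
#' non-vessel analysis mask.
#'
#' @slot probe character, `"NBDG"` or `"TMRE"`.
#' @slot endpointTime numeric, requested endpoint time (min).
#' @slot selectedTime numeric, acquired time actually used (min).
#' @slot image numeric matrix; NA outside `analysisMask`.
#' @slot analysisMask logical matrix, TRUE = analyzed (non-vessel).
#' @export
setClass("EndpointMap",
  representation(
    probe = "character", endpointTime = "numeric",
    selectedTime = "numeric", image = "matrix", analysisMask = "matrix"
  )
)

setValidity("EndpointMap", function(object) {
  msg <- character()
  if (!identical(dim(object@image), dim(object@analysisMask)))
    msg <- c(msg, "'image' and 'analysisMask' must have the same shape")
  if (any(!is.na(object@image[!object@analysisMask])))
    msg <- c(msg, "'image' must be NA outside 'analysisMask'")
  if (length(msg)) msg else TRUE
})

#' Synthetic scene ground truth
#'
#' Per-pixel ground-truth fields for a generated tongue-like scene:
#' vessel geometry, chromophore concentration-pathlength products,
#' oxygen saturation, metabolic fluorescence amplitudes and the kinetic
#' rate constants used to render uptake series.
#'
#' @slot vesselMask logical matrix, TRUE = vessel.
#' @slot cHbO2True,cHbTrue numeric matrices, concentration x pathlength
#'   products (indicator units, M cm); zero outside the vessel mask.
#' @slot stO2True numeric matrix, fraction; NA outside vessels.
#' @slot metabolicNbdg,metabolicTmre numeric matrices, fluorescence
#'   amplitudes (arbitrary units).
#' @slot kineticParams list with elements `nbdg` (tauRise, tauDecay,
#'   min) and `tmre` (tau, min).
#' @slot tumorLike logical scalar.
#' @slot pixelPitch numeric, micrometres per pixel.
#' @export
setClass("SceneTruth",
  representation(
    vesselMask = "matrix", cHbO2True = "matrix", cHbTrue = "matrix",
    stO2True = "matrix", metabolicNbdg = "matrix",
    metabolicTmre = "matrix", kineticParams = "list",
    tumorLike = "logical", pixelPitch = "numeric"
  )
)

setValidity("SceneTruth", function(object) {
  msg <- character()
  d <- dim(object@vesselMask)
  for (nm in c("cHbO2True", "cHbTrue", "stO2True",
               "metabolicNbdg", "metabolicTmre"))
    if (!identical(dim(slot(object, nm)), d))
      msg <- c(msg, sprintf("'%s' must match the vessel-mask shape", nm))
  out <- !object@vesselMask
  if (any(object@cHbO2True[out] != 0) || any(object@cHbTrue[out] != 0))
    msg <- c(msg, "chromophore fields must be zero outside the vessel mask")
  tot <- object@cHbO2True + object@cHbTrue
  pos <- tot > 0
  if (any(abs(object@stO2True[pos] - object@cHbO2True[pos] / tot[pos]) > 1e-9,
          na.rm = TRUE))
    msg <- c(msg, "stO2True must equal cHbO2True / (cHbO2True + cHbTrue)")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @describeIn SpectralStack-class image data array
#' @param object,x a pipeline container object
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname SpectralStack-class
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))

#' @rdname SpectralStack-class
#' @export
setGeneric("calIntensity", function(object) standardGeneric("calIntensity"))

#' @rdname FluorSeries-class
#' @export
setGeneric("probeTimes", function(object) standardGeneric("probeTimes"))

#' @rdname SceneTruth-class
#' @export
setGeneric("vesselMask", function(object) standardGeneric("vesselMask"))

#' @rdname ChromophoreMaps-class
#' @export
setGeneric("acceptedMask", function(object) standardGeneric("acceptedMask"))

setMethod("frames", "SpectralStack", function(object) object@frames)
setMethod("frames", "FluorSeries", function(object) object@frames)
setMethod("wavelengths", "SpectralStack", function(object) object@wavelengths)
setMethod("wavelengths", "AbsorbanceStack", function(object) object@wavelengths)
setMethod("calIntensity", "SpectralStack", function(object) object@calIntensity)
setMethod("probeTimes", "FluorSeries", function(object) object@times)
setMethod("vesselMask", "SceneTruth", function(object) object@vesselMask)
setMethod("vesselMask", "VascularMaps", function(object) object@vesselMask)
setMethod("acceptedMask", "ChromophoreMaps", function(object) object@accepted)

#' @rdname VascularMaps-class
#' @param object a `VascularMaps` object
#' @export
setGeneric("stO2Map", function(object) standardGeneric("stO2Map"))

#' @rdname VascularMaps-class
#' @export
setGeneric("thbMap", function(object) standardGeneric("thbMap"))

setMethod("stO2Map", "VascularMaps", function(object) object@StO2)
setMethod("thbMap", "VascularMaps", function(object) object@THb)

## ---- show methods ----

.dimTxt <- function(d) paste(d, collapse = " x ")

setMethod("show", "SpectralStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("SpectralStack: %s px, %d wavelengths (%s nm)\n",
              .dimTxt(d[1:2]), d[3L],
              paste(object@wavelengths, collapse = ", ")))
  cat(sprintf("  cal intensity: %s counts; standard reflectance %.2f\n",
              paste(signif(object@calIntensity, 4), collapse = ", "),
              object@standardReflectance))
})

setMethod("show", "AbsorbanceStack", function(object) {
  d <- dim(object@A)
  cat(sprintf("AbsorbanceStack: %s px, %d wavelengths; %.1f%% valid pixels\n",
              .dimTxt(d[1:2]), d[3L], 100 * mean(object@valid)))
})

setMethod("show", "ChromophoreMaps", function(object) {
  cat(sprintf("ChromophoreMaps: %s px; %.1f%% accepted (R2 >= %.2f)\n",
              .dimTxt(dim(object@b0)),
              100 * mean(object@accepted, na.rm = TRUE),
              object@r2Threshold))
})

setMethod("show", "VascularMaps", function(object) {
  n <- sum(!is.na(object@StO2))
  cat(sprintf("VascularMaps: %s px; %d vessel pixels with defined StO2\n",
              .dimTxt(dim(object@StO2)), n))
  if (n)
    cat(sprintf("  mean StO2 %.3f; mean THb %.3g (indicator units)\n",
                mean(object@StO2, na.rm = TRUE),
                mean(object@THb, na.rm = TRUE)))
})

setMethod("show", "FluorSeries", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FluorSeries (%s): %s px, %d timepoints over %.0f min\n",
              object@probe, .dimTxt(d[1:2]), d[3L], max(object@times)))
})

setMethod("show", "EndpointMap", function(object) {
  cat(sprintf(
    "EndpointMap (%s%d): frame at %.0f min; %d analyzed pixels\n",
    if (object@probe == "NBDG") "2-NBDG" else "TMRE",
    round(object@endpointTime), object@selectedTime,
    sum(object@analysisMask)))
})

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf("SceneTruth: %s px, %s; vessel fraction %.1f%%\n",
              .dimTxt(dim(object@vesselMask)),
              if (object@tumorLike) "tumor-like" else "normal",
              100 * mean(object@vesselMask)))
})
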