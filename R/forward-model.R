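## Forward optical model: the modified Beer-Lambert absorbance
##   A(lambda) = b0 + b1 * muEff(lambda) + epsHbO2(lambda) * C_HbO2
##                + epsHb(lambda) * C_Hb
## run forward to synthesize dark-field diffuse-reflectance stacks,
##   I_tissue = I_cal * 10^(-A)   (base-10 convention throughout).

#' Render a diffuse-reflectance stack from scene ground truth
#'
#' Runs the modified Beer-Lambert model forward: for every pixel and
#' wavelength, absorbance is the background term `b0 + b1 * muEff`
#' plus the extinction-weighted chromophore products of that pixel
#' (zero outside vessels), and the rendered tissue intensity is
#' `calIntensity * 10^(-A)`.
#'
#' @param scene a [SceneTruth-class] object.
#' @param background an `optical_background` covering the wavelengths.
#' @param ext an `extinction_table` covering the wavelengths.
#' @param b0 source-variability offset (dimensionless), >= 0.
#' @param b1 effective-attenuation scale (cm), >= 0.
#' @param calIntensity reflectance-standard intensity, counts (> 0);
#'   recycled across wavelengths.
#' @param noiseCv multiplicative Gaussian noise coefficient of
#'   variation applied to the rendered intensities (0 = noiseless).
#' @param seed integer seed used when `noiseCv > 0`.
#' @return A [SpectralStack-class].
#' @examples
#' sc <- simulateTongueScene(64, 64, seed = 1)
#' st <- renderReflectance(sc, defaultTongueBackground(),
#'                         builtinExtinctionTable())
#' @export
renderReflectance <- function(scene, background, ext, b0 = 0.1, b1 = 0.01,
                              calIntensity = 1000, noiseCv = 0,
                              seed = 1L) {
  stopifnot(is(scene, "SceneTruth"))
  if (b0 < 0 || b1 < 0) stop("b0 and b1 must be non-negative")
  if (any(calIntensity <= 0)) stop("calIntensity must be positive")
  wl <- background$wavelength
  if (!identical(as.numeric(ext$wavelength), as.numeric(wl)))
    stop("extinction table and background must cover the same wavelengths")
  h <- nrow(scene@vesselMask); w <- ncol(scene@vesselMask)
  nl <- length(wl)
  cal <- rep_len(calIntensity, nl)
  A <- array(0, c(h, w, nl))
  for (l in seq_len(nl)) {
    A[, , l] <- b0 + b1 * background$muEff[l] +
      ext$epsHbO2[l] * scene@cHbO2True + ext$epsHb[l] * scene@cHbTrue
  }
  itissue <- sweep(10^(-A), 3L, cal, `*`)
  if (noiseCv > 0) {
    withr::with_seed(as.integer(seed), {
      itissue <- itissue * (1 + noiseCv * stats::rnorm(length(itissue)))
    })
    itissue[itissue < 0] <- 0
  }
  SpectralStack(itissue, wl, cal)
}

#' Phantom series specification
#'
#' Describes one group of homogeneous tissue-mimicking hemoglobin
#' phantoms: a fixed reduced-scattering level with stepwise hemoglobin
#' additions spanning a range of average absorption coefficients.
#'
#' @param scatteringLevel reduced scattering, cm^-1 (average over the
#'   imaging band); phantom groups use 5, 10 and 15.
#' @param absorptionSteps increasing hemoglobin absorption
#'   coefficients, cm^-1 (average over the band); default five steps
#'   spanning 1.0-5.5.
#' @param sto2 hemoglobin oxygen saturation of the phantom, fraction;
#'   default 0.95 (freshly oxygenated hemoglobin).
#' @param noiseCv multiplicative noise CV, default 0.01.
#' @param seed integer seed.
#' @return A validated list of class `phantom_spec`.
#' @export
phantomSpec <- function(scatteringLevel = 10,
                        absorptionSteps = seq(1.0, 5.5, length.out = 5),
                        sto2 = 0.95, noiseCv = 0.01, seed = 1L) {
  if (any(diff(absorptionSteps) <= 0))
    stop("'absorptionSteps' must be increasing")
  if (sto2 < 0 || sto2 > 1) stop("'sto2' must lie in [0, 1]")
  if (noiseCv < 0) stop("'noiseCv' must be >= 0")
  structure(list(scatteringLevel = scatteringLevel,
                 absorptionSteps = absorptionSteps, sto2 = sto2,
                 noiseCv = noiseCv, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Simulate a homogeneous hemoglobin phantom series
#'
#' Generates one homogeneous diffuse-reflectance stack per hemoglobin
#' absorption step of a phantom group, with known true total-hemoglobin
#' indicator and oxygen saturation. The hemoglobin concentration at
#' each step is the one whose mean extinction over the imaging
#' wavelengths produces the requested average absorption coefficient;
#' the true THb indicator is the concentration-pathlength product, so
#' it is proportional to the absorption step.
#'
#' @param spec a [phantomSpec()] object.
#' @param ext an `extinction_table`.
#' @param size image side length in pixels (homogeneous frames).
#' @param pathLength effective optical path length, cm; folds into the
#'   indicator units of the chromophore products.
#' @param backgroundMuA non-hemoglobin background absorption, cm^-1.
#' @param b0,b1,calIntensity forward-model parameters as in
#'   [renderReflectance()].
#' @return A list with `stacks` (list of [SpectralStack-class]) and
#'   `truth` (data frame: `step`, `muaStep`, `thbTrue`, `stO2True`,
#'   `scatteringLevel`, `seed`).
#' @examples
#' ph <- simulatePhantomSeries(phantomSpec(noiseCv = 0), size = 8)
#' ph$truth
#' @export
simulatePhantomSeries <- function(spec = phantomSpec(),
                                  ext = builtinExtinctionTable(),
                                  size = 32, pathLength = 0.1,
                                  backgroundMuA = 0.2, b0 = 0.1,
                                  b1 = 0.01, calIntensity = 1000) {
  stopifnot(inherits(spec, "phantom_spec"))
  wl <- ext$wavelength
  background <- opticalBackground(wl, muA = backgroundMuA,
                                  muSPrime = spec$scatteringLevel)
  ## mean molar extinction of the hemoglobin mixture over the band
  epsMix <- spec$sto2 * ext$epsHbO2 + (1 - spec$sto2) * ext$epsHb
  epsAvg <- mean(epsMix)
  stacks <- vector("list", length(spec$absorptionSteps))
  truth <- data.frame(step = seq_along(spec$absorptionSteps),
                      muaStep = spec$absorptionSteps,
                      thbTrue = NA_real_, stO2True = spec$sto2,
                      scatteringLevel = spec$scatteringLevel,
                      seed = spec$seed)
  for (i in seq_along(spec$absorptionSteps)) {
    mua <- spec$absorptionSteps[i]
    conc <- mua / (log(10) * epsAvg)     # molar concentration
    thb <- conc * pathLength             # indicator units (M cm)
    truth$thbTrue[i] <- thb
    scene <- .homogeneousScene(size, cHbO2 = spec$sto2 * thb,
                               cHb = (1 - spec$sto2) * thb)
    stacks[[i]] <- renderReflectance(
      scene, background, ext, b0 = b0, b1 = b1,
      calIntensity = calIntensity, noiseCv = spec$noiseCv,
      seed = deriveSeed(spec$seed, i))
  }
  list(stacks = stacks, truth = truth)
}

## All-vessel homogeneous scene used for phantom emulation.
.homogeneousScene <- function(size, cHbO2, cHb) {
  ones <- matrix(TRUE, size, size)
  tot <- cHbO2 + cHb
  new("SceneTruth",
      vesselMask = ones,
      cHbO2True = matrix(cHbO2, size, size),
      cHbTrue = matrix(cHb, size, size),
      stO2True = matrix(if (tot > 0) cHbO2 / tot else NA_real_, size, size),
      metabolicNbdg = matrix(0, size, size),
      metabolicTmre = matrix(0, size, size),
      kineticParams = list(),
      tumorLike = FALSE, pixelPitch = 1.04)
}
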