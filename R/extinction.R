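#' Hemoglobin extinction coefficients at the imaging wavelengths
#'
#' Molar extinction coefficients of oxy- and deoxy-hemoglobin at the
#' four dark-field imaging wavelengths (540, 560, 580, 610 nm), taken
#' from the standard compiled hemoglobin extinction dataset (the
#' Prahl/OMLC compilation of Gratzer's and Kollias' measurements).
#' Values are at the filter center wavelengths; the 10-nm filter
#' bandwidth is ignored by default (see [bandAverageExtinction()] for
#' band-averaging a dense table).
#'
#' @param wavelengths which wavelengths (nm) to return; must be a
#'   subset of 540/560/580/610 for the builtin table.
#' @return A data frame of class `extinction_table` with columns
#'   `wavelength` (nm), `epsHbO2` and `epsHb` (cm^-1 M^-1).
#' @examples
#' builtinExtinctionTable()
#' @export
builtinExtinctionTable <- function(wavelengths = c(540, 560, 580, 610)) {
  tab <- data.frame(
    wavelength = c(540, 560, 580, 610),
    epsHbO2 = c(53236, 32613.2, 50104, 1506),
    epsHb = c(46592, 53788, 37020, 9443.4)
  )
  if (!all(wavelengths %in% tab$wavelength))
    stop("builtin extinction table covers 540/560/580/610 nm only; ",
         "supply a custom table via extinctionTable() for other bands")
  extinctionTable(tab[match(wavelengths, tab$wavelength), , drop = FALSE])
}

#' Validate an extinction table
#'
#' @param tab data frame with columns `wavelength`, `epsHbO2`, `epsHb`
#'   (cm^-1 M^-1), one row per imaging wavelength.
#' @return The table, validated, with class `extinction_table`.
#' @export
extinctionTable <- function(tab) {
  need <- c("wavelength", "epsHbO2", "epsHb")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("extinction table is missing column(s): ",
         paste(miss, collapse = ", "))
  tab <- as.data.frame(tab)[, need]
  rownames(tab) <- NULL
  if (any(diff(tab$wavelength) <= 0))
    stop("extinction-table wavelengths must be strictly increasing")
  if (any(!is.finite(as.matrix(tab))) || any(tab$epsHbO2 <= 0) ||
      any(tab$epsHb <= 0))
    stop("extinction coefficients must be finite and positive")
  class(tab) <- c("extinction_table", "data.frame")
  tab
}

#' Band-average a dense extinction table over filter bandwidths
#'
#' Trapezoidal average of a densely sampled extinction spectrum over
#' `center +/- halfwidth` for each filter, for users who want to account
#' for the finite (10 nm) filter bandwidth instead of sampling the
#' spectrum at the center wavelength.
#'
#' @param dense data frame with columns `wavelength`, `epsHbO2`,
#'   `epsHb` sampled finely enough to cover every band.
#' @param centers filter center wavelengths (nm).
#' @param halfwidth half bandwidth (nm), default 5.
#' @return An `extinction_table` at the center wavelengths with
#'   band-averaged coefficients.
#' @export
bandAverageExtinction <- function(dense, centers = c(540, 560, 580, 610),
                                  halfwidth = 5) {
  dense <- as.data.frame(dense)
  avg <- function(center, col) {
    grid <- seq(center - halfwidth, center + halfwidth, length.out = 21)
    y <- stats::approx(dense$wavelength, dense[[col]], xout = grid)$y
    if (any(is.na(y)))
      stop("dense table does not cover the band around ", center, " nm")
    trapz(grid, y) / (2 * halfwidth)
  }
  extinctionTable(data.frame(
    wavelength = centers,
    epsHbO2 = vapply(centers, avg, 0, col = "epsHbO2"),
    epsHb = vapply(centers, avg, 0, col = "epsHb")
  ))
}

#' Effective attenuation coefficient (diffusion approximation)
#'
#' \eqn{\mu_{eff} = \sqrt{3 \mu_a (\mu_a + \mu_s')}}.
#'
#' @param muA absorption coefficient(s), cm^-1.
#' @param muSPrime reduced scattering coefficient(s), cm^-1.
#' @return Effective attenuation coefficient(s), cm^-1.
#' @examples
#' effectiveAttenuation(1, 10)
#' @export
effectiveAttenuation <- function(muA, muSPrime) {
  if (any(muA < 0) || any(muSPrime < 0))
    stop("optical coefficients must be non-negative")
  sqrt(3 * muA * (muA + muSPrime))
}

#' Background optical properties per wavelength
#'
#' Bundles the background (non-hemoglobin) absorption and reduced
#' scattering of the tissue or phantom matrix, and the derived
#' effective attenuation coefficient used as the \eqn{\mu_{eff}}
#' regressor of the modified Beer-Lambert model.
#'
#' @param wavelengths nm, strictly increasing.
#' @param muA background absorption per wavelength, cm^-1.
#' @param muSPrime reduced scattering per wavelength, cm^-1.
#' @param muEff optional: supply effective attenuation directly (cm^-1)
#'   instead of `muA`/`muSPrime`.
#' @return Data frame of class `optical_background` with columns
#'   `wavelength`, `muA`, `muSPrime`, `muEff`.
#' @examples
#' opticalBackground(c(540, 560, 580, 610), muA = 0.5, muSPrime = 10)
#' @export
opticalBackground <- function(wavelengths, muA = NULL, muSPrime = NULL,
                              muEff = NULL) {
  n <- length(wavelengths)
  if (any(diff(wavelengths) <= 0))
    stop("'wavelengths' must be strictly increasing")
  if (is.null(muEff)) {
    if (is.null(muA) || is.null(muSPrime))
      stop("supply either muEff or both muA and muSPrime")
    muA <- rep_len(muA, n); muSPrime <- rep_len(muSPrime, n)
    muEff <- effectiveAttenuation(muA, muSPrime)
  } else {
    muEff <- rep_len(muEff, n)
    if (any(muEff < 0)) stop("muEff must be non-negative")
    muA <- rep_len(muA %||% NA_real_, n)
    muSPrime <- rep_len(muSPrime %||% NA_real_, n)
  }
  out <- data.frame(wavelength = as.numeric(wavelengths), muA = muA,
                    muSPrime = muSPrime, muEff = muEff)
  class(out) <- c("optical_background", "data.frame")
  out
}

#' Placeholder background optical properties for mouse tongue
#'
#' Representative soft-tissue background optical properties at the four
#' imaging wavelengths. These are configuration placeholders typical of
#' weakly pigmented soft tissue in the 540-610 nm window, not measured
#' tongue values; replace them with measured properties when available.
#'
#' @param wavelengths nm (subset of 540/560/580/610).
#' @return An `optical_background` data frame.
#' @export
defaultTongueBackground <- function(wavelengths = c(540, 560, 580, 610)) {
  ref <- data.frame(
    wavelength = c(540, 560, 580, 610),
    muA = c(0.60, 0.55, 0.50, 0.35),
    muSPrime = c(11.0, 10.5, 10.0, 9.0)
  )
  idx <- match(wavelengths, ref$wavelength)
  if (any(is.na(idx)))
    stop("default background covers 540/560/580/610 nm only")
  opticalBackground(ref$wavelength[idx], muA = ref$muA[idx],
                    muSPrime = ref$muSPrime[idx])
}
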