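## Spectral unmixing: modified Beer-Lambert model fitted per pixel by
## exact non-negative least squares.
##
## With four wavelengths and four coefficients (b0, b1, C_HbO2, C_Hb)
## the NNLS optimum can be found exactly by enumerating all 2^4
## support sets: the global optimum is the minimum-residual feasible
## least-squares solution over the support sets (at the optimum the
## gradient vanishes on the support, so the optimum restricted to its
## support is that support's unconstrained LS solution). Enumeration
## is batched across pixels with one QR per support set, which makes
## whole-image unmixing a handful of dense matrix products.

#' Compute per-pixel absorbance from a reflectance stack
#'
#' Base-10 absorbance `A = log10(calIntensity / Itissue)` per pixel
#' and wavelength. Pixels with non-positive intensity at any
#' wavelength are flagged invalid (NA absorbance), not dropped.
#'
#' @param stack a [SpectralStack-class].
#' @param logBase logarithm base, default 10 (the convention of molar
#'   extinction coefficients). When changed (e.g. to `exp(1)`), the
#'   extinction and attenuation columns of the design matrix must be
#'   rescaled consistently (base-10 coefficients times `log(10)` for
#'   natural log).
#' @return An [AbsorbanceStack-class].
#' @examples
#' s <- SpectralStack(array(100, c(4, 4, 4)), c(540, 560, 580, 610), 1000)
#' computeAbsorbance(s)
#' @export
computeAbsorbance <- function(stack, logBase = 10) {
  stopifnot(is(stack, "SpectralStack"))
  fr <- stack@frames
  nl <- length(stack@wavelengths)
  A <- array(NA_real_, dim(fr))
  bad <- matrix(FALSE, dim(fr)[1L], dim(fr)[2L])
  for (l in seq_len(nl)) {
    f <- fr[, , l]
    ok <- is.finite(f) & f > 0
    bad <- bad | !ok
    a <- matrix(NA_real_, nrow(f), ncol(f))
    a[ok] <- log(stack@calIntensity[l] / f[ok], base = logBase)
    A[, , l] <- a
  }
  valid <- !bad
  if (!any(valid))
    stop("no valid pixels: all intensities are non-positive or non-finite")
  for (l in seq_len(nl)) {
    a <- A[, , l]; a[!valid] <- NA_real_; A[, , l] <- a
  }
  new("AbsorbanceStack", A = A, wavelengths = stack@wavelengths,
      valid = valid)
}

#' Build the modified Beer-Lambert design matrix
#'
#' One row per wavelength, columns ordered
#' `(b0, b1, C_HbO2, C_Hb)`: an intercept, the effective attenuation
#' coefficient, and the two hemoglobin extinction spectra.
#'
#' @param wavelengths nm, in stack frame order.
#' @param background an `optical_background` covering them.
#' @param ext an `extinction_table` covering them.
#' @return Numeric matrix, `length(wavelengths)` x 4, with column
#'   names `b0`, `b1`, `cHbO2`, `cHb`.
#' @examples
#' buildDesignMatrix(c(540, 560, 580, 610), defaultTongueBackground(),
#'                   builtinExtinctionTable())
#' @export
buildDesignMatrix <- function(wavelengths, background, ext) {
  ib <- match(wavelengths, background$wavelength)
  ie <- match(wavelengths, ext$wavelength)
  if (any(is.na(ib)))
    stop("background is missing wavelength(s): ",
         paste(wavelengths[is.na(ib)], collapse = ", "))
  if (any(is.na(ie)))
    stop("extinction table is missing wavelength(s): ",
         paste(wavelengths[is.na(ie)], collapse = ", "))
  M <- cbind(b0 = 1, b1 = background$muEff[ib],
             cHbO2 = ext$epsHbO2[ie], cHb = ext$epsHb[ie])
  rownames(M) <- as.character(wavelengths)
  M
}

## Exact batched NNLS by support-set enumeration.
## M: m x p design; B: m x N right-hand sides (columns = pixels).
## Returns list(x: p x N coefficients, rss: length-N residual sums of
## squares). Exact for small p (2^p support sets).
nnlsBatch <- function(M, B) {
  m <- nrow(M); p <- ncol(M); N <- ncol(B)
  bestRss <- colSums(B^2)              # empty support: x = 0
  bestX <- matrix(0, p, N)
  for (code in seq_len(2^p - 1L)) {
    S <- which(bitwAnd(code, bitwShiftL(1L, 0:(p - 1L))) > 0L)
    MS <- M[, S, drop = FALSE]
    qrS <- qr(MS)
    if (qrS$rank < length(S)) next     # rank-deficient face: skip
    xS <- qr.coef(qrS, B)
    if (length(S) == 1L) xS <- matrix(xS, 1L)
    feas <- colSums(xS < -1e-10) == 0L
    if (!any(feas)) next
    R <- B - MS %*% xS
    rss <- colSums(R^2)
    take <- feas & (rss < bestRss - 1e-12)
    if (any(take)) {
      bestRss[take] <- rss[take]
      bestX[, take] <- 0
      bestX[S, take] <- pmax(xS[, take, drop = FALSE], 0)
    }
  }
  list(x = bestX, rss = bestRss)
}

#' Fit the Beer-Lambert model at one pixel
#'
#' Solves `min || M x - a ||` subject to `x >= 0` for all four
#' coefficients, and computes the coefficient of determination of the
#' fit about the mean of the absorbance vector. The fit is accepted
#' when `r2 >= r2Threshold`; a flat absorbance vector (zero total sum
#' of squares) is rejected with `r2 = NA`.
#'
#' @param absorbance numeric vector, one absorbance per wavelength.
#' @param design design matrix from [buildDesignMatrix()] (or any
#'   m x p non-negative-coefficient design).
#' @param r2Threshold acceptance threshold, default 0.9.
#' @return A list with `b0`, `b1`, `cHbO2`, `cHb` (named after the
#'   design columns), `r2`, `accepted`, `rss`.
#' @examples
#' M <- buildDesignMatrix(c(540, 560, 580, 610), defaultTongueBackground(),
#'                        builtinExtinctionTable())
#' a <- as.vector(M %*% c(0.1, 0.01, 2e-6, 1e-6))
#' fitPixel(a, M)
#' @export
fitPixel <- function(absorbance, design, r2Threshold = 0.9) {
  if (any(!is.finite(absorbance)))
    stop("'absorbance' must be finite")
  if (length(absorbance) != nrow(design))
    stop("'absorbance' length must equal the number of design rows")
  sol <- nnlsBatch(design, matrix(absorbance, ncol = 1L))
  sst <- sum((absorbance - mean(absorbance))^2)
  r2 <- if (sst > 0) 1 - sol$rss / sst else NA_real_
  out <- as.list(sol$x[, 1L])
  names(out) <- colnames(design) %||% paste0("x", seq_len(ncol(design)))
  c(out, list(r2 = r2,
              accepted = !is.na(r2) && r2 >= r2Threshold,
              rss = sol$rss))
}

#' Unmix a whole absorbance stack into chromophore maps
#'
#' Applies the per-pixel non-negative Beer-Lambert fit to every valid
#' pixel of the stack; invalid pixels propagate as missing. Reports
#' the fraction of accepted fits.
#'
#' @param absStack an [AbsorbanceStack-class].
#' @param design design matrix from [buildDesignMatrix()], rows in the
#'   stack's wavelength order, columns `(b0, b1, cHbO2, cHb)`.
#' @param r2Threshold per-pixel acceptance threshold on R-squared.
#' @param verbose emit a message with the acceptance fraction.
#' @return A [ChromophoreMaps-class].
#' @export
unmixStack <- function(absStack, design, r2Threshold = 0.9,
                       verbose = FALSE) {
  stopifnot(is(absStack, "AbsorbanceStack"))
  d <- dim(absStack@A)
  h <- d[1L]; w <- d[2L]; nl <- d[3L]
  if (nrow(design) != nl)
    stop("design matrix rows must match the number of wavelengths")
  valid <- absStack@valid
  idx <- which(valid)
  B <- matrix(aperm(absStack@A, c(3L, 1L, 2L)), nrow = nl)[, idx,
                                                           drop = FALSE]
  sol <- nnlsBatch(design, B)
  sst <- colSums(sweep(B, 2L, colMeans(B), `-`)^2)
  r2 <- ifelse(sst > 0, 1 - sol$rss / sst, NA_real_)
  accepted <- !is.na(r2) & r2 >= r2Threshold
  blank <- matrix(NA_real_, h, w)
  fill <- function(v) { m <- blank; m[idx] <- v; m }
  accMat <- matrix(NA, h, w); accMat[idx] <- accepted
  maps <- new("ChromophoreMaps",
              b0 = fill(sol$x[1L, ]), b1 = fill(sol$x[2L, ]),
              cHbO2 = fill(sol$x[3L, ]), cHb = fill(sol$x[4L, ]),
              r2 = fill(r2), accepted = accMat,
              r2Threshold = r2Threshold)
  if (verbose)
    message(sprintf("unmixed %d pixels: %.1f%% accepted (R2 >= %.2f)",
                    length(idx), 100 * mean(accepted), r2Threshold))
  maps
}

#' Derive vascular parameter maps from chromophore fits
#'
#' HbO2 and Hb indicators are the fitted chromophore products, the
#' total-hemoglobin indicator is their sum, and StO2 is the
#' oxyhemoglobin fraction, all restricted to accepted fits inside the
#' vessel mask. Pixels with zero total hemoglobin have undefined StO2.
#'
#' @param chrom a [ChromophoreMaps-class].
#' @param vesselMask logical matrix (TRUE = vessel), same shape.
#' @return A [VascularMaps-class].
#' @export
makeVascularMaps <- function(chrom, vesselMask) {
  stopifnot(is(chrom, "ChromophoreMaps"))
  vesselMask <- vesselMask > 0
  if (!identical(dim(vesselMask), dim(chrom@cHb)))
    stop("'vesselMask' must match the map shape")
  if (!any(vesselMask)) stop("'vesselMask' selects no pixels")
  keep <- vesselMask & !is.na(chrom@accepted) & chrom@accepted
  msk <- function(v) { v[!keep] <- NA_real_; v }
  hbo2 <- msk(chrom@cHbO2)
  hb <- msk(chrom@cHb)
  thb <- hbo2 + hb
  sto2 <- ifelse(!is.na(thb) & thb > 0, hbo2 / thb, NA_real_)
  new("VascularMaps", StO2 = sto2, THb = thb, Hb = hb, HbO2 = hbo2,
      vesselMask = vesselMask)
}
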