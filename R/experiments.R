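## In-silico re-runs of the instrument-characterization experiments:
## the hemoglobin phantom linearity study and the fluorescence
## dilution linearity study, each simulated with the package's forward
## models and analyzed with its estimation pipeline.

#' Phantom total-hemoglobin linearity experiment
#'
#' Simulates the full hemoglobin phantom grid — three reduced
#' scattering levels (5/10/15 cm^-1) with five hemoglobin steps each
#' spanning average absorption coefficients of 1.0-5.5 cm^-1, 1%
#' multiplicative noise — unmixes every stack with the non-negative
#' Beer-Lambert fit, and regresses the mean estimated THb indicator
#' per phantom on the true hemoglobin concentration.
#'
#' @param seed integer seed for the noise streams.
#' @param size phantom frame side length, px.
#' @param noiseCv multiplicative noise CV, default 0.01.
#' @return List with `r2` (coefficient of determination of the
#'   estimated-vs-true regression), `n` (number of phantoms) and the
#'   per-phantom `table` (scattering level, true and estimated THb).
#' @export
phantomLinearityExperiment <- function(seed = 1L, size = 32L,
                                       noiseCv = 0.01) {
  ext <- builtinExtinctionTable()
  rows <- list()
  for (s in c(5, 10, 15)) {
    spec <- phantomSpec(scatteringLevel = s, noiseCv = noiseCv,
                        seed = deriveSeed(seed, s))
    ph <- simulatePhantomSeries(spec, ext, size = size)
    bg <- opticalBackground(ext$wavelength, muA = 0.2, muSPrime = s)
    M <- buildDesignMatrix(ext$wavelength, bg, ext)
    for (i in seq_along(ph$stacks)) {
      maps <- unmixStack(computeAbsorbance(ph$stacks[[i]]), M)
      rows[[length(rows) + 1L]] <- data.frame(
        scatteringLevel = s,
        thbTrue = ph$truth$thbTrue[i],
        thbEst = mean(maps@cHbO2 + maps@cHb, na.rm = TRUE),
        accepted = mean(maps@accepted, na.rm = TRUE))
    }
  }
  tab <- do.call(rbind, rows)
  fit <- stats::lm(thbEst ~ thbTrue, data = tab)
  list(r2 = summary(fit)$r.squared, n = nrow(tab), table = tab)
}

#' Fluorescence dilution linearity experiment
#'
#' Simulates dilution series of both metabolic probes (2-NBDG 0-8 uM,
#' TMRE 0-70 nM; nine concentration points each) at three scattering
#' levels with 2% multiplicative noise, regresses mean intensity on
#' concentration per probe pooling the scattering levels, and reports
#' the coefficient of determination per probe.
#'
#' @param seed integer seed.
#' @param noiseCv multiplicative noise CV, default 0.02.
#' @return List with `r2` (named: NBDG, TMRE), `minR2`, `n` (points
#'   per probe) and the pooled `table`.
#' @export
dilutionLinearityExperiment <- function(seed = 1L, noiseCv = 0.02) {
  probes <- list(
    NBDG = list(conc = seq(0, 8, length.out = 9), gain = 120,
                offset = 0L),
    TMRE = list(conc = seq(0, 70, length.out = 9), gain = 14,
                offset = 100L))
  r2 <- c(NBDG = NA_real_, TMRE = NA_real_)
  tabs <- list()
  for (p in names(probes)) {
    cfg <- probes[[p]]
    dat <- do.call(rbind, lapply(c(5, 10, 15), function(s) {
      d <- simulateDilutionSeries(cfg$conc, gain = cfg$gain,
                                  noiseCv = noiseCv,
                                  seed = deriveSeed(seed, s + cfg$offset))
      d$scatteringLevel <- s
      d$probe <- p
      d
    }))
    fit <- stats::lm(meanIntensity ~ concentration, data = dat)
    r2[p] <- summary(fit)$r.squared
    tabs[[p]] <- dat
  }
  list(r2 = r2, minR2 = min(r2), n = nrow(tabs[[1L]]),
       table = do.call(rbind, tabs))
}
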