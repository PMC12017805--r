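## Tongue-like synthetic scenes and fluorescence uptake simulation.
## These generators stand in for the instrument and the animals: every
## downstream stage of the pipeline can be exercised against known
## per-pixel ground truth.

#' Scene generator parameters
#'
#' Ground-truth field parameters for normal and tumor-like scenes.
#' Tumor-like scenes have lower mean oxygen saturation, a lower
#' total-hemoglobin indicator, higher metabolic amplitudes and
#' spatially rougher metabolic fields than normal scenes, mirroring
#' the direction of the in-vivo group differences.
#'
#' @param tumorLike logical; tumor-like parameter set?
#' @return A named list of generator parameters.
#' @export
sceneParams <- function(tumorLike = FALSE) {
  if (tumorLike)
    list(stO2Mean = 0.45, stO2Spread = 0.06,
         thbScale = 1.3e-6, thbSpread = 0.25,
         nbdgAmp = 110, tmreAmp = 95,
         coarseCv = 0.15, fineCv = 0.30,
         coarseGrid = 6L, fineGrid = 24L)
  else
    list(stO2Mean = 0.75, stO2Spread = 0.06,
         thbScale = 2.4e-6, thbSpread = 0.25,
         nbdgAmp = 60, tmreAmp = 50,
         coarseCv = 0.18, fineCv = 0,
         coarseGrid = 6L, fineGrid = 24L)
}

#' Simulate a tongue-like vascular scene with ground truth
#'
#' Draws smooth branching vessel ribbons onto the field of view and
#' fills per-pixel ground-truth maps: chromophore
#' concentration-pathlength products and oxygen saturation inside
#' vessels, and smooth (normal) or rough (tumor-like) metabolic
#' fluorescence amplitude fields over the whole scene. Vessel widths
#' span roughly 4-25 um at the default 1.04 um/px pitch.
#'
#' @param height,width scene size in pixels, >= 64.
#' @param nVessels number of primary vessel ribbons.
#' @param tumorLike logical; use the tumor-like parameter set.
#' @param seed integer seed; identical arguments give identical scenes.
#' @param params generator parameters, see [sceneParams()].
#' @param pixelPitch micrometres per pixel (metadata only).
#' @return A [SceneTruth-class] object.
#' @examples
#' sc <- simulateTongueScene(64, 64, seed = 7)
#' mean(vesselMask(sc))
#' @export
simulateTongueScene <- function(height = 256, width = 256, nVessels = 5,
                                tumorLike = FALSE, seed = 1L,
                                params = sceneParams(tumorLike),
                                pixelPitch = 1.04) {
  if (height < 64 || width < 64)
    stop("scene dimensions must be at least 64 x 64")
  withr::with_seed(as.integer(seed), {
    mask <- .drawVessels(height, width, nVessels)
    sto2 <- clamp(params$stO2Mean +
                    params$stO2Spread * smoothField(height, width, 8L),
                  0.05, 0.98)
    thb <- params$thbScale *
      clamp(1 + params$thbSpread * smoothField(height, width, 8L), 0.2, 2)
    cHbO2 <- ifelse(mask, sto2 * thb, 0)
    cHb <- ifelse(mask, (1 - sto2) * thb, 0)
    metField <- function(amp) {
      f <- 1 + params$coarseCv * smoothField(height, width, params$coarseGrid)
      if (params$fineCv > 0)
        f <- f + params$fineCv * smoothField(height, width, params$fineGrid)
      amp * clamp(f, 0.05, 3)
    }
    nbdg <- metField(params$nbdgAmp)
    tmre <- metField(params$tmreAmp)
  })
  new("SceneTruth",
      vesselMask = mask, cHbO2True = cHbO2, cHbTrue = cHb,
      stO2True = ifelse(mask, cHbO2 / (cHbO2 + cHb), NA_real_),
      metabolicNbdg = nbdg, metabolicTmre = tmre,
      kineticParams = list(nbdg = list(tauRise = 1, tauDecay = 80),
                           tmre = list(tau = 20)),
      tumorLike = tumorLike, pixelPitch = pixelPitch)
}

## Random-walk vessel ribbons with occasional branches. Vessel
## coverage is kept inside [minFrac, maxFrac] of the scene: vessels
## that would push coverage past maxFrac are discarded (the first,
## always a minor vessel, is kept), and minor vessels are topped up
## while coverage is below minFrac. Caller owns the RNG state.
.drawVessels <- function(h, w, nVessels, minFrac = 0.02,
                         maxFrac = 0.20) {
  mask <- matrix(FALSE, h, w)
  stamp <- function(y, x, r) {
    ys <- max(1L, floor(y - r)):min(h, ceiling(y + r))
    xs <- max(1L, floor(x - r)):min(w, ceiling(x + r))
    dy2 <- (ys - y)^2
    dx2 <- (xs - x)^2
    mask[ys, xs] <<- mask[ys, xs] | (outer(dy2, dx2, `+`) <= r^2)
  }
  walk <- function(y, x, ang, r, maxSteps) {
    centers <- matrix(NA_real_, maxSteps, 2L)
    for (s in seq_len(maxSteps)) {
      y <- y + sin(ang); x <- x + cos(ang)
      if (y < -r || y > h + r || x < -r || x > w + r) {
        centers <- centers[seq_len(s - 1L), , drop = FALSE]
        break
      }
      if (s %% 2L == 0L) stamp(y, x, r)
      centers[s, ] <- c(y, x)
      ang <- ang + stats::rnorm(1L, 0, 0.12)
    }
    centers[stats::complete.cases(centers), , drop = FALSE]
  }
  drawOne <- function(major) {
    side <- sample.int(4L, 1L)
    start <- switch(side,
      c(1, stats::runif(1, 1, w), pi / 2),    # top, heading down
      c(h, stats::runif(1, 1, w), -pi / 2),   # bottom, heading up
      c(stats::runif(1, 1, h), 1, 0),         # left, heading right
      c(stats::runif(1, 1, h), w, pi))        # right, heading left
    ang <- start[3L] + stats::rnorm(1L, 0, 0.3)
    r <- if (major) stats::runif(1L, 3, 6) else stats::runif(1L, 1, 3)
    maxSteps <- as.integer(1.5 * max(h, w))
    centers <- walk(start[1L], start[2L], ang, r, maxSteps)
    ## one branch per primary vessel, at half the parent caliber
    if (nrow(centers) > 20L && stats::runif(1L) < 0.7) {
      at <- centers[sample.int(nrow(centers), 1L), ]
      walk(at[1L], at[2L], stats::runif(1L, 0, 2 * pi),
           max(1, r / 2), maxSteps %/% 2L)
    }
  }
  for (v in seq_len(nVessels)) {
    before <- mask
    drawOne(major = v > 1L && stats::runif(1L) < 0.3)
    if (v > 1L && mean(mask) > maxFrac) {
      mask <- before
      break
    }
  }
  tries <- 0L
  while (mean(mask) < minFrac && tries < 12L) {
    drawOne(major = FALSE)
    tries <- tries + 1L
  }
  mask
}

#' Fluorescence uptake kinetic kernels
#'
#' Dimensionless uptake kinetics, `k(0) = 0`. 2-NBDG follows a
#' difference of exponentials normalized to unit peak (default rate
#' constants place the peak near 4.4 min, inside the observed 2-6 min
#' window, with a gradual washout that retains about half the peak
#' intensity at 60 min); TMRE follows a saturating
#' mono-exponential `1 - exp(-t/tau)` (default tau = 20 min puts the
#' signal above 95% of plateau by 60 min).
#'
#' @param t time, minutes.
#' @param tauRise,tauDecay 2-NBDG rise and washout time constants, min.
#' @param tau TMRE saturation time constant, min.
#' @return Kernel value(s) in `[0, 1]` (2-NBDG peaks at exactly 1).
#' @examples
#' nbdgKernel(3.84)
#' tmreKernel(60)
#' @export
nbdgKernel <- function(t, tauRise = 1, tauDecay = 80) {
  if (tauDecay <= tauRise) stop("tauDecay must exceed tauRise")
  raw <- exp(-t / tauDecay) - exp(-t / tauRise)
  tPeak <- log(tauDecay / tauRise) * tauRise * tauDecay /
    (tauDecay - tauRise)
  peak <- exp(-tPeak / tauDecay) - exp(-tPeak / tauRise)
  raw / peak
}

#' @rdname nbdgKernel
#' @export
tmreKernel <- function(t, tau = 20) 1 - exp(-t / tau)

#' Default acquisition timepoints for a probe
#'
#' Dense early sampling to resolve the 2-NBDG peak, then sparser
#' sampling out to the endpoint (60 min for 2-NBDG, 80 min for TMRE).
#'
#' @param probe `"NBDG"` or `"TMRE"`.
#' @return Numeric vector of minutes, starting at 0.
#' @export
defaultTimepoints <- function(probe = c("NBDG", "TMRE")) {
  probe <- match.arg(probe)
  if (probe == "NBDG") c(0:8, 10, 12, 15, 20, 25, 30, 40, 50, 60)
  else c(0, 2, 5, 10, 15, 20, 25, 30, 40, 50, 60, 70, 80)
}

#' Simulate a fluorescence uptake image series
#'
#' Per-pixel intensity is `baseline + amplitude * k(t)` with the
#' probe's kinetic kernel and the scene's metabolic amplitude field;
#' vessel pixels are rendered darker by a fixed attenuation factor
#' (hemoglobin absorption dims fluorescence over vessels), and
#' multiplicative Gaussian noise is applied per pixel.
#'
#' @param scene a [SceneTruth-class].
#' @param probe `"NBDG"` or `"TMRE"`.
#' @param timepoints minutes, strictly increasing, starting at 0;
#'   default [defaultTimepoints()].
#' @param noiseCv multiplicative noise CV.
#' @param seed integer seed.
#' @param baselineLevel pre-injection tissue fluorescence, counts.
#' @param vesselAttenuation multiplicative dimming over vessel pixels.
#' @param gain,exposure acquisition metadata (defaults: gain 15 for
#'   2-NBDG, 25 for TMRE; exposure 1000 ms).
#' @return A [FluorSeries-class].
#' @examples
#' sc <- simulateTongueScene(64, 64, seed = 2)
#' fs <- simulateFluorSeries(sc, "NBDG", noiseCv = 0)
#' @export
simulateFluorSeries <- function(scene, probe = c("NBDG", "TMRE"),
                                timepoints = NULL, noiseCv = 0.01,
                                seed = 1L, baselineLevel = 20,
                                vesselAttenuation = 0.5, gain = NULL,
                                exposure = 1000) {
  probe <- match.arg(probe)
  stopifnot(is(scene, "SceneTruth"))
  timepoints <- timepoints %||% defaultTimepoints(probe)
  if (timepoints[1L] != 0 || any(diff(timepoints) <= 0))
    stop("'timepoints' must be strictly increasing and start at 0")
  kp <- scene@kineticParams
  k <- if (probe == "NBDG")
    nbdgKernel(timepoints, kp$nbdg$tauRise, kp$nbdg$tauDecay)
  else
    tmreKernel(timepoints, kp$tmre$tau)
  amp <- if (probe == "NBDG") scene@metabolicNbdg else scene@metabolicTmre
  att <- ifelse(scene@vesselMask, vesselAttenuation, 1)
  h <- nrow(amp); w <- ncol(amp)
  fr <- array(0, c(h, w, length(timepoints)))
  for (i in seq_along(timepoints))
    fr[, , i] <- att * (baselineLevel + amp * k[i])
  if (noiseCv > 0) {
    withr::with_seed(deriveSeed(seed, if (probe == "NBDG") 11L else 13L), {
      fr <- fr * (1 + noiseCv * stats::rnorm(length(fr)))
    })
    fr[fr < 0] <- 0
  }
  FluorSeries(probe, timepoints, fr,
              gain = gain %||% if (probe == "NBDG") 15 else 25,
              exposure = exposure)
}

#' Simulate a fluorophore dilution series
#'
#' Mean fluorescence intensity versus fluorophore concentration for a
#' well-mixed scattering solution: `intensity = gain * c * (1 + noise)`
#' with multiplicative Gaussian noise. Used to characterize probe
#' linearity over the biologically relevant range (2-NBDG 0-8 uM,
#' TMRE 0-70 nM).
#'
#' @param concentrations non-negative concentrations (uM or nM).
#' @param gain counts per concentration unit.
#' @param noiseCv multiplicative noise CV.
#' @param seed integer seed.
#' @return Data frame with columns `concentration`, `meanIntensity`.
#' @examples
#' simulateDilutionSeries(0:8, gain = 50, noiseCv = 0)
#' @export
simulateDilutionSeries <- function(concentrations, gain = 100,
                                   noiseCv = 0.02, seed = 1L) {
  if (any(concentrations < 0))
    stop("'concentrations' must be non-negative")
  withr::with_seed(as.integer(seed), {
    noise <- stats::rnorm(length(concentrations), 0, noiseCv)
  })
  data.frame(concentration = as.numeric(concentrations),
             meanIntensity = gain * concentrations * (1 + noise))
}

#' Fit a kinetic kernel to an uptake curve
#'
#' Least-squares fit of `amplitude * k(t)` to a background-subtracted
#' kinetic curve, with the amplitude profiled out analytically and the
#' rate constants optimized numerically (L-BFGS-B). The baseline point
#' at t = 0 is included (kernel value 0 there).
#'
#' @param curve data frame with columns `time` and `meanIntensity`
#'   (background-subtracted), as returned by [uptakeKinetics()].
#' @param probe `"NBDG"` or `"TMRE"`.
#' @param start optional named start values (`tauRise`/`tauDecay` or
#'   `tau`).
#' @return List with `amplitude`, `pars` (named rate constants, min),
#'   `fitted`, and the residual sum of squares `rss`.
#' @export
fitKineticCurve <- function(curve, probe = c("NBDG", "TMRE"),
                            start = NULL) {
  probe <- match.arg(probe)
  t <- curve$time; y <- curve$meanIntensity
  ## NBDG is parameterized as (tauRise, tauDecay - tauRise) so the
  ## box constraint keeps tauDecay > tauRise throughout the search
  kfun <- if (probe == "NBDG") {
    function(p) nbdgKernel(t, p[1L], p[1L] + p[2L])
  } else {
    function(p) tmreKernel(t, p[1L])
  }
  obj <- function(p) {
    k <- kfun(p)
    a <- sum(y * k) / sum(k * k)
    sum((y - a * k)^2)
  }
  p0 <- if (probe == "NBDG") {
    s <- start %||% list(tauRise = 1, tauDecay = 10)
    c(s$tauRise, s$tauDecay - s$tauRise)
  } else {
    c((start %||% list(tau = 15))$tau)
  }
  lower <- rep(0.05, length(p0))
  upper <- rep(200, length(p0))
  fit <- stats::optim(p0, obj, method = "L-BFGS-B", lower = lower,
                      upper = upper,
                      control = list(factr = 1e4, maxit = 500L))
  k <- kfun(fit$par)
  a <- sum(y * k) / sum(k * k)
  pars <- if (probe == "NBDG")
    c(tauRise = fit$par[1L], tauDecay = fit$par[1L] + fit$par[2L])
  else c(tau = fit$par[1L])
  list(amplitude = a, pars = pars, fitted = a * k, rss = fit$value)
}
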