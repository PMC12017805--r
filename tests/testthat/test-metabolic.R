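mkSeries <- function(frames, times, probe = "NBDG")
  FluorSeries(probe, times, frames)

test_that("background subtraction is exact, linear and clipped at zero", {
  base <- matrix(runif(36, 10, 20), 6)
  fr <- array(c(base, base, base + 5, base - 3), c(6, 6, 4))
  s <- mkSeries(fr, c(0, 2, 4, 6))
  sub <- subtractBackground(s)
  expect_equal(frames(sub)[, , 2L], matrix(0, 6, 6))       # identical frame
  expect_equal(frames(sub)[, , 3L], matrix(5, 6, 6))       # + constant
  expect_equal(frames(sub)[, , 4L], matrix(0, 6, 6))       # clipped
  signed <- subtractBackground(s, clip = FALSE)
  expect_equal(frames(signed)[, , 4L], matrix(-3, 6, 6))
})

test_that("pixel-shift registration recovers constructed translations", {
  set.seed(15)
  img <- matrix(rnorm(40 * 40), 40)
  expect_identical(registerShift(img, img), c(dy = 0L, dx = 0L))

  moved <- mpfm:::shiftImage(img, 2L, -1L, fill = 0)
  expect_identical(registerShift(img, moved, maxShift = 5),
                   c(dy = 2L, dx = -1L))

  ## monotone structure so correlation rises toward the out-of-window
  ## true shift and the best in-window candidate sits on the boundary
  ramp <- outer(1:40, 1:40, function(y, x) y + 0.5 * x)
  far <- mpfm:::shiftImage(ramp, 15L, 0L, fill = 0)
  expect_warning(sh <- registerShift(ramp, far, maxShift = 10),
                 "boundary")
  expect_true(all(abs(sh) <= 10))

  expect_error(registerShift(img, img, maxShift = 35), "overlap")
})

test_that("analysis mask combines both vessel sources with the shift on the reflectance mask only", {
  h <- 12; w <- 12
  none <- matrix(FALSE, h, w)
  expect_true(all(buildAnalysisMask(none, none, dilate = 0)))

  refl <- none; refl[2, 2] <- TRUE
  fluor <- none; fluor[9, 9] <- TRUE
  am <- buildAnalysisMask(refl, fluor, dilate = 0)
  expect_false(am[2, 2])
  expect_false(am[9, 9])
  expect_equal(sum(!am), 2L)

  ## a recorded displacement of (1, 0) moves the reflectance mask back
  ## by (-1, 0); the fluorescence mask must not move
  amS <- buildAnalysisMask(refl, fluor, shift = c(1L, 0L), dilate = 0)
  expect_false(amS[1, 2])
  expect_true(amS[2, 2])
  expect_false(amS[9, 9])

  ## dilation absorbs vessel-edge bleed
  expect_equal(sum(!buildAnalysisMask(refl, none, dilate = 1)), 9L)

  full <- matrix(TRUE, h, w)
  expect_error(buildAnalysisMask(full, full, dilate = 0), "empty")
})

test_that("uptake kinetics average the masked pixels and shrink with larger vessel masks", {
  fr <- array(0, c(8, 8, 3))
  fr[, , 2] <- 4; fr[, , 3] <- 6
  s <- mkSeries(fr, c(0, 5, 10))
  mask <- matrix(TRUE, 8, 8)
  cv <- uptakeKinetics(s, mask)
  expect_equal(cv$meanIntensity, c(0, 4, 6))
  expect_equal(unique(cv$nPixels), 64L)

  smallMask <- mask; smallMask[1:4, ] <- FALSE
  expect_lt(unique(uptakeKinetics(s, smallMask)$nPixels), 64L)
  expect_error(uptakeKinetics(s, matrix(FALSE, 8, 8)), "no pixels")
})

test_that("simulated uptake curves peak in 2-6 min (2-NBDG) and reach 95% plateau by 60 min (TMRE)", {
  sc <- simulateTongueScene(64, 64, seed = 8)
  amask <- !vesselMask(sc)

  nb <- uptakeKinetics(simulateFluorSeries(sc, "NBDG", noiseCv = 0), amask)
  expect_gte(nb$time[which.max(nb$meanIntensity)], 2)
  expect_lte(nb$time[which.max(nb$meanIntensity)], 6)

  tm <- uptakeKinetics(simulateFluorSeries(sc, "TMRE", noiseCv = 0), amask)
  expect_true(all(diff(tm$meanIntensity) >= 0))
  fit <- fitKineticCurve(tm, "TMRE")
  expect_gte(tm$meanIntensity[tm$time == 60] / fit$amplitude, 0.95)
})

test_that("kinetic fits recover the generating rate constants from noiseless curves", {
  sc <- simulateTongueScene(64, 64, seed = 12)
  amask <- !vesselMask(sc)

  nb <- uptakeKinetics(simulateFluorSeries(sc, "NBDG", noiseCv = 0), amask)
  fitN <- fitKineticCurve(nb, "NBDG")
  truthN <- sc@kineticParams$nbdg
  expect_equal(unname(fitN$pars["tauRise"]), truthN$tauRise,
               tolerance = 0.01)
  expect_equal(unname(fitN$pars["tauDecay"]), truthN$tauDecay,
               tolerance = 0.01)
  ampTrue <- mean(sc@metabolicNbdg[amask])
  expect_equal(fitN$amplitude, ampTrue, tolerance = 0.01)

  tm <- uptakeKinetics(simulateFluorSeries(sc, "TMRE", noiseCv = 0), amask)
  fitT <- fitKineticCurve(tm, "TMRE")
  expect_equal(unname(fitT$pars["tau"]), 20, tolerance = 0.01)
})

test_that("endpoint frames are selected nearest in time with earlier tie-break", {
  fr <- array(rep(1:5, each = 16), c(4, 4, 5))
  mask <- matrix(TRUE, 4, 4)

  s <- mkSeries(fr, c(0, 30, 58, 62, 80))
  ep <- endpointMap(s, mask, endpointTime = 60)
  expect_equal(ep@selectedTime, 58)                 # tie -> earlier

  sExact <- mkSeries(fr, c(0, 30, 60, 62, 80))
  expect_equal(endpointMap(sExact, mask, 60)@selectedTime, 60)

  expect_error(endpointMap(mkSeries(fr, c(0, 5, 10, 15, 20)), mask, 60),
               "within 5")

  ## endpoint equals the identically preprocessed series frame
  sub <- subtractBackground(s)
  expect_equal(ep@image, frames(sub)[, , 3L])
  ## masking: outside pixels are missing
  half <- mask; half[, 1:2] <- FALSE
  epH <- endpointMap(s, half, endpointTime = 60)
  expect_true(all(is.na(epH@image[, 1:2])))
})

test_that("2-NBDG60 and TMRE80 with the 20-min injection stagger share a wall-clock instant", {
  ## TMRE injected at clock 0, 2-NBDG at clock 20: the NBDG frame at 60
  ## min post-NBDG and the TMRE frame at 80 min post-TMRE coincide, so
  ## the two default endpoints describe the same instant.
  sc <- simulateTongueScene(64, 64, seed = 3)
  epN <- endpointMap(simulateFluorSeries(sc, "NBDG", noiseCv = 0),
                     !vesselMask(sc))
  epT <- endpointMap(simulateFluorSeries(sc, "TMRE", noiseCv = 0),
                     !vesselMask(sc))
  expect_equal(epN@selectedTime, 60)
  expect_equal(epT@selectedTime, 80)
})
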