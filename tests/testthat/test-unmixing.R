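test_that("absorbance follows the base-10 calibration identities", {
  fr <- array(500, c(4, 4, 4))
  st <- SpectralStack(fr, c(540, 560, 580, 610), calIntensity = 500)
  ab <- computeAbsorbance(st)
  expect_equal(as.vector(ab@A), rep(0, 64))

  st10 <- SpectralStack(fr / 10, c(540, 560, 580, 610), calIntensity = 500)
  expect_equal(as.vector(computeAbsorbance(st10)@A), rep(1, 64))

  ## a single dead pixel is flagged invalid, the rest computed
  fr[2, 3, 1] <- 0
  abBad <- computeAbsorbance(SpectralStack(fr, c(540, 560, 580, 610), 500))
  expect_false(abBad@valid[2, 3])
  expect_true(all(abBad@valid[-(4 * 2 + 2)]))
  expect_true(all(is.na(abBad@A[2, 3, ])))
  expect_equal(abBad@A[1, 1, 1], 0)

  allBad <- SpectralStack(array(-1, c(2, 2, 4)), c(540, 560, 580, 610), 500)
  expect_error(computeAbsorbance(allBad), "no valid pixels")

  ## switching the log base rescales absorbance by ln(10)
  abE <- computeAbsorbance(st10, logBase = exp(1))
  expect_equal(abE@A, computeAbsorbance(st10)@A * log(10))
})

test_that("design matrix has intercept, diffusion-approximation mu_eff and both extinction spectra", {
  bg <- opticalBackground(c(540, 560, 580, 610), muA = c(1, 2, 3, 4),
                          muSPrime = c(10, 11, 12, 13))
  M <- buildDesignMatrix(c(540, 560, 580, 610), bg,
                         builtinExtinctionTable())
  expect_identical(dim(M), c(4L, 4L))
  expect_equal(unname(M[, 1L]), rep(1, 4))
  ## hand computation of sqrt(3 mu_a (mu_a + mu_s'))
  expect_equal(unname(M[, 2L]),
               sqrt(3 * c(1, 2, 3, 4) * (c(1, 2, 3, 4) + c(10, 11, 12, 13))))
  expect_equal(unname(M[, 3L]), builtinExtinctionTable()$epsHbO2)
  expect_equal(unname(M[, 4L]), builtinExtinctionTable()$epsHb)

  expect_error(buildDesignMatrix(c(540, 600), bg, builtinExtinctionTable()),
               "600")
})

test_that("fitPixel recovers non-negative coefficients exactly when constraints are inactive", {
  set.seed(42)
  M <- matrix(abs(rnorm(16)) + 0.1, 4, 4,
              dimnames = list(NULL, c("b0", "b1", "cHbO2", "cHb")))
  x <- c(0.1, 0.2, 0.5, 0.3)
  fit <- fitPixel(as.vector(M %*% x), M)
  expect_equal(unlist(fit[c("b0", "b1", "cHbO2", "cHb")]),
               c(b0 = 0.1, b1 = 0.2, cHbO2 = 0.5, cHb = 0.3),
               tolerance = 1e-8)
  expect_equal(fit$r2, 1)
  expect_true(fit$accepted)
})

test_that("fitPixel matches the KKT enumeration oracle and lsqnonneg when constraints bind", {
  set.seed(7)
  for (i in 1:200) {
    M <- matrix(rnorm(16, sd = 2), 4, 4)
    xTrue <- rnorm(4)            # mixed signs force active constraints
    a <- as.vector(M %*% xTrue) + rnorm(4, sd = 0.1)
    fit <- fitPixel(a, M, r2Threshold = 0.9)
    xHat <- unlist(fit[1:4], use.names = FALSE)
    rImpl <- sqrt(sum((a - M %*% xHat)^2))
    xOracle <- nnlsKktOracle(M, a)
    rOracle <- sqrt(sum((a - M %*% xOracle)^2))
    expect_lt(abs(rImpl - rOracle), 1e-6)
    xP <- pracma::lsqnonneg(M, a)$x
    expect_lt(abs(rImpl - sqrt(sum((a - M %*% xP)^2))), 1e-6)
  }
})

test_that("a flat absorbance vector yields the zero fit and is rejected", {
  fit <- fitPixel(rep(0, 4), testDesign())
  expect_equal(unlist(fit[1:4], use.names = FALSE), rep(0, 4))
  expect_true(is.na(fit$r2))
  expect_false(fit$accepted)
  expect_error(fitPixel(c(1, NA, 1, 1), testDesign()), "finite")
})

test_that("unmixStack propagates invalid pixels and honors the acceptance threshold", {
  bg <- defaultTongueBackground()
  ext <- builtinExtinctionTable()
  sc <- homogScene(6, 2e-6, 1e-6)
  st <- renderReflectance(sc, bg, ext)
  fr <- frames(st)
  fr[3, 4, 2] <- 0                      # kill one pixel at one band
  stBad <- SpectralStack(fr, wavelengths(st), calIntensity(st))
  maps <- unmixStack(computeAbsorbance(stBad), testDesign())
  expect_true(is.na(maps@cHbO2[3, 4]))
  expect_true(is.na(maps@r2[3, 4]))
  expect_identical(sum(is.na(maps@cHbO2)), 1L)   # only that pixel missing

  ## an unreachable threshold rejects every noisy pixel
  stN <- renderReflectance(sc, bg, ext, noiseCv = 0.05, seed = 2)
  mapsN <- unmixStack(computeAbsorbance(stN), testDesign(),
                      r2Threshold = 1.01)
  expect_equal(sum(mapsN@accepted, na.rm = TRUE), 0L)
})

test_that("vascular maps satisfy the StO2/THb identities and reject empty masks", {
  mk <- function(hbo2, hb) {
    one <- matrix(1, 2, 2)
    new("ChromophoreMaps", b0 = one * 0, b1 = one * 0,
        cHbO2 = one * hbo2, cHb = one * hb, r2 = one,
        accepted = matrix(TRUE, 2, 2), r2Threshold = 0.9)
  }
  mask <- matrix(TRUE, 2, 2)
  vm <- makeVascularMaps(mk(1, 1), mask)
  expect_equal(as.vector(vm@StO2), rep(0.5, 4))
  expect_equal(as.vector(vm@THb), rep(2, 4))

  expect_equal(as.vector(makeVascularMaps(mk(2, 0), mask)@StO2), rep(1, 4))

  vm0 <- makeVascularMaps(mk(0, 0), mask)
  expect_true(all(is.na(vm0@StO2)))
  expect_equal(as.vector(vm0@THb), rep(0, 4))

  expect_error(makeVascularMaps(mk(1, 1), matrix(FALSE, 2, 2)),
               "no pixels")
})

test_that("maps are scale-equivariant and StO2 stays within [0, 1] under noise", {
  bg <- defaultTongueBackground()
  ext <- builtinExtinctionTable()
  sc <- simulateTongueScene(64, 64, seed = 6)
  st <- renderReflectance(sc, bg, ext, noiseCv = 0.02, seed = 3)
  M <- testDesign()
  m1 <- unmixStack(computeAbsorbance(st), M)
  stScaled <- SpectralStack(frames(st) * 7.5, wavelengths(st),
                            calIntensity(st) * 7.5)
  m2 <- unmixStack(computeAbsorbance(stScaled), M)
  expect_equal(m1@cHbO2, m2@cHbO2, tolerance = 1e-12)
  expect_equal(m1@r2, m2@r2, tolerance = 1e-12)

  vm <- makeVascularMaps(m1, vesselMask(sc))
  s <- vm@StO2[!is.na(vm@StO2)]
  expect_true(all(s >= 0 & s <= 1))
})

test_that("phantom StO2 is recovered to a 0.05 median under 1% noise", {
  ext <- builtinExtinctionTable()
  errs <- c()
  for (s in c(5, 10, 15)) {
    ph <- simulatePhantomSeries(phantomSpec(scatteringLevel = s,
                                            noiseCv = 0.01, seed = s),
                                ext, size = 24)
    M <- buildDesignMatrix(ext$wavelength,
                           opticalBackground(ext$wavelength, muA = 0.2,
                                             muSPrime = s), ext)
    for (i in seq_along(ph$stacks)) {
      m <- unmixStack(computeAbsorbance(ph$stacks[[i]]), M)
      sto2 <- m@cHbO2 / (m@cHbO2 + m@cHb)
      errs <- c(errs, abs(sto2 - ph$truth$stO2True[i]))
    }
  }
  expect_lte(median(errs, na.rm = TRUE), 0.05)
})

test_that("estimated THb is non-decreasing along a single-chromophore dilution", {
  bg <- defaultTongueBackground()
  ext <- builtinExtinctionTable()
  M <- testDesign()
  thbTrue <- seq(5e-7, 5e-6, length.out = 6)
  est <- vapply(thbTrue, function(thb) {
    st <- renderReflectance(homogScene(4, thb, 0), bg, ext)
    maps <- unmixStack(computeAbsorbance(st), M)
    mean(maps@cHbO2 + maps@cHb)
  }, 0)
  expect_true(all(diff(est) >= 0))
})
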