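test_that("builtin extinction table covers the four imaging bands and round-trips through CSV", {
  tab <- builtinExtinctionTable()
  expect_identical(tab$wavelength, c(540, 560, 580, 610))
  expect_true(all(tab$epsHbO2 > 0) && all(tab$epsHb > 0))
  expect_true(all(diff(tab$wavelength) > 0))

  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  back <- extinctionTable(utils::read.csv(f))
  expect_identical(back$epsHbO2, tab$epsHbO2)
  expect_identical(back$epsHb, tab$epsHb)

  expect_error(builtinExtinctionTable(c(540, 600)), "custom table")
})

test_that("band-averaging a flat dense spectrum reproduces the flat value", {
  dense <- data.frame(wavelength = seq(500, 650, by = 1),
                      epsHbO2 = 100, epsHb = 50)
  avg <- bandAverageExtinction(dense)
  expect_equal(avg$epsHbO2, rep(100, 4))
  expect_equal(avg$epsHb, rep(50, 4))
  expect_error(bandAverageExtinction(dense[dense$wavelength > 538, ]),
               "cover the band")
})

test_that("forward model obeys the zero-absorption identity and base-10 convention", {
  bg <- defaultTongueBackground()
  ext <- builtinExtinctionTable()
  empty <- homogScene(8, 0, 0)
  st0 <- renderReflectance(empty, bg, ext, b0 = 0, b1 = 0,
                           calIntensity = 800)
  expect_equal(as.vector(frames(st0)), rep(800, 8 * 8 * 4))

  ## A = b0 = 1 at every wavelength -> Itissue = Ical / 10
  st1 <- renderReflectance(empty, bg, ext, b0 = 1, b1 = 0,
                           calIntensity = 800)
  expect_equal(as.vector(frames(st1)), rep(80, 8 * 8 * 4))

  expect_error(renderReflectance(empty, bg, ext, b0 = -1), "non-negative")
})

test_that("noiseless render-unmix roundtrip recovers per-pixel chromophores", {
  bg <- defaultTongueBackground()
  ext <- builtinExtinctionTable()
  sc <- simulateTongueScene(64, 64, seed = 11)
  st <- renderReflectance(sc, bg, ext)
  maps <- unmixStack(computeAbsorbance(st),
                     buildDesignMatrix(wavelengths(st), bg, ext))
  vessel <- vesselMask(sc) & (sc@cHbO2True + sc@cHbTrue) > 0
  relErr <- function(est, true)
    max(abs(est[vessel] - true[vessel]) / pmax(true[vessel], 1e-12))
  expect_lt(relErr(maps@cHbO2, sc@cHbO2True), 1e-8)
  expect_lt(relErr(maps@cHb, sc@cHbTrue), 1e-8)
})

test_that("phantom intensity decreases with hemoglobin and generators are seed-deterministic", {
  ph <- simulatePhantomSeries(phantomSpec(noiseCv = 0.01, seed = 5),
                              size = 8)
  expect_length(ph$stacks, 5L)
  mean560 <- vapply(ph$stacks, function(s) mean(frames(s)[, , 2L]), 0)
  expect_true(all(diff(mean560) < 0))
  expect_true(all(diff(ph$truth$thbTrue) > 0))

  ## zero noise: the seed is irrelevant
  a <- simulatePhantomSeries(phantomSpec(noiseCv = 0, seed = 1), size = 8)
  b <- simulatePhantomSeries(phantomSpec(noiseCv = 0, seed = 2), size = 8)
  expect_identical(frames(a$stacks[[3L]]), frames(b$stacks[[3L]]))

  ## with noise: same seed bit-identical, different seed not
  c1 <- simulatePhantomSeries(phantomSpec(noiseCv = 0.01, seed = 7), size = 8)
  c2 <- simulatePhantomSeries(phantomSpec(noiseCv = 0.01, seed = 7), size = 8)
  c3 <- simulatePhantomSeries(phantomSpec(noiseCv = 0.01, seed = 8), size = 8)
  expect_identical(frames(c1$stacks[[1L]]), frames(c2$stacks[[1L]]))
  expect_false(identical(frames(c1$stacks[[1L]]), frames(c3$stacks[[1L]])))
})

test_that("tongue scenes respect the generator contracts", {
  for (seed in c(1, 9, 23)) {
    sc <- simulateTongueScene(96, 96, seed = seed)
    frac <- mean(vesselMask(sc))
    expect_gte(frac, 0.02)
    expect_lte(frac, 0.20)
    ## StO2 identity wherever hemoglobin is present
    tot <- sc@cHbO2True + sc@cHbTrue
    pos <- tot > 0
    expect_equal(sc@stO2True[pos], (sc@cHbO2True / tot)[pos])
    ## chromophores vanish outside vessels
    expect_true(all(sc@cHbO2True[!vesselMask(sc)] == 0))
  }

  a <- simulateTongueScene(64, 64, seed = 4)
  b <- simulateTongueScene(64, 64, seed = 4)
  expect_identical(a@vesselMask, b@vesselMask)
  expect_identical(a@metabolicNbdg, b@metabolicNbdg)

  tum <- simulateTongueScene(64, 64, tumorLike = TRUE, seed = 4)
  expect_gt(mean(a@stO2True, na.rm = TRUE),
            mean(tum@stO2True, na.rm = TRUE))

  expect_error(simulateTongueScene(32, 32), "at least 64")
})

test_that("kinetic kernels place the 2-NBDG peak in 2-6 min and the TMRE plateau by 60 min", {
  grid <- seq(0, 60, by = 0.1)
  tPeak <- grid[which.max(nbdgKernel(grid))]
  expect_gte(tPeak, 2)
  expect_lte(tPeak, 6)
  expect_equal(nbdgKernel(0), 0)
  ## saturating kernel: k(60)/k(inf) with tau = 20 is 1 - exp(-3)
  expect_gte(tmreKernel(60) / 1, 0.95)
  expect_equal(tmreKernel(60), 1 - exp(-3))

  sc <- simulateTongueScene(64, 64, seed = 2)
  fs <- simulateFluorSeries(sc, "NBDG", noiseCv = 0)
  sub <- subtractBackground(fs)
  expect_true(all(frames(sub)[, , 1L] == 0))
  expect_error(simulateFluorSeries(sc, "NBDG", timepoints = c(1, 2)),
               "start at 0")
})

test_that("dilution series is linear in concentration with a zero intercept", {
  d0 <- simulateDilutionSeries(c(0, 2, 4, 8), gain = 50, noiseCv = 0)
  expect_equal(d0$meanIntensity, c(0, 100, 200, 400))

  dn <- simulateDilutionSeries(c(0, 2, 4), gain = 50, noiseCv = 0.05,
                               seed = 3)
  expect_equal(dn$meanIntensity[1L], 0)   # multiplicative noise at c = 0

  expect_equal(cor(d0$concentration, d0$meanIntensity)^2, 1)

  expect_identical(simulateDilutionSeries(0:8, seed = 9),
                   simulateDilutionSeries(0:8, seed = 9))
  expect_error(simulateDilutionSeries(-1), "non-negative")
})
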