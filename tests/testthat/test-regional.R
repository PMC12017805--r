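test_that("nonant partition splits both axes with the remainder in the last band", {
  p3 <- nonantPartition(3, 3)
  expect_equal(nrow(p3), 9L)
  expect_true(all(p3$row1 - p3$row0 == 1L))
  expect_true(all(p3$col1 - p3$col0 == 1L))

  p300 <- nonantPartition(300, 300)
  expect_true(all(p300$row1 - p300$row0 == 100L))

  p10 <- nonantPartition(10, 10)
  expect_equal(unique(p10$row1 - p10$row0)[order(unique(p10$row1 - p10$row0))],
               c(3L, 4L))
  ## row-major nonant order: nonant 0 top-left, nonant 2 top-right
  expect_equal(p10$row0[1:3], c(0L, 0L, 0L))
  expect_equal(p10$col0[1:3], c(0L, 3L, 6L))

  expect_error(nonantPartition(2, 10), "at least 3 x 3")
})

test_that("pixel-count-weighted nonant means reconstruct the global masked mean", {
  set.seed(19)
  map <- matrix(rnorm(50 * 70), 50, 70)
  map[sample(length(map), 400)] <- NA
  mask <- matrix(runif(50 * 70) > 0.3, 50, 70)
  nm <- nonantMeans(map, mask)
  ok <- nm$nValid > 0
  weighted <- sum(nm$mean[ok] * nm$nValid[ok]) / sum(nm$nValid[ok])
  expect_equal(weighted, mean(map[mask & !is.na(map)]),
               tolerance = 1e-10)

  ## constant map; and an empty nonant yields a missing mean
  cmap <- matrix(2.5, 9, 9)
  expect_equal(nonantMeans(cmap)$mean, rep(2.5, 9))
  holeMask <- matrix(TRUE, 9, 9); holeMask[1:3, 1:3] <- FALSE
  nmHole <- nonantMeans(cmap, holeMask)
  expect_true(is.na(nmHole$mean[1]))
  expect_equal(nmHole$nValid[1], 0L)
})

test_that("global-max normalization rescales to peak 1 and leaves Pearson r unchanged", {
  expect_equal(as.vector(normalizeGlobalMax(c(2, 4, 8))),
               c(0.25, 0.5, 1))
  expect_equal(as.vector(normalizeGlobalMax(5)), 1)
  expect_error(normalizeGlobalMax(c(-2, -1)), "positive")

  set.seed(2)
  x <- runif(20, 1, 9); y <- x + rnorm(20)
  r0 <- correlateNonants(x, y)$r
  r1 <- correlateNonants(as.vector(normalizeGlobalMax(x)), y)$r
  expect_equal(r0, r1)
})

test_that("kernel density curves integrate to one and match the normal density at zero", {
  set.seed(123)
  x <- rnorm(1e5)
  d <- kdeDistribution(x)
  integral <- sum(diff(d$grid) * (head(d$density, -1) + tail(d$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-3)
  at0 <- approx(d$grid, d$density, xout = 0)$y
  expect_equal(at0, 1 / sqrt(2 * pi), tolerance = 0.05)
  expect_equal(attr(d, "mean"), mean(x))

  ## interleaved half-samples give nearly the same curve
  y <- rnorm(4000)
  d1 <- kdeDistribution(y[c(TRUE, FALSE)])
  d2 <- kdeDistribution(y[c(FALSE, TRUE)])
  common <- seq(-2, 2, length.out = 101)
  diffMax <- max(abs(approx(d1$grid, d1$density, common)$y -
                       approx(d2$grid, d2$density, common)$y))
  expect_lt(diffMax, 0.1)

  expect_error(kdeDistribution(rep(1, 50)), "equal")
  expect_error(kdeDistribution(c(1, 2, 3)), "at least 10")
})

test_that("group comparison reproduces the pooled-variance Student t by hand", {
  x <- c(3.1, 2.8, 3.5, 3.0, 3.3)
  y <- c(2.1, 2.6, 2.2, 2.4, 2.0)
  res <- compareGroups(x, y)
  ## textbook pooled formula
  sp2 <- ((5 - 1) * var(x) + (5 - 1) * var(y)) / (5 + 5 - 2)
  tHand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  pHand <- 2 * pt(-abs(tHand), df = 8)
  expect_equal(res$statistic, tHand, tolerance = 1e-12)
  expect_equal(res$pValue, pHand, tolerance = 1e-12)
  expect_equal(res$df, 8)

  ## identical groups: no difference at all
  same <- compareGroups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$pValue, 1)

  ## separated groups with tiny jitter: overwhelming evidence
  set.seed(4)
  sep <- compareGroups(rnorm(4, 0, 1e-4), 1 + rnorm(4, 0, 1e-4))
  expect_lt(sep$pValue, 1e-6)

  expect_error(compareGroups(1, c(1, 2)), "at least 2")
})

test_that("the Student t p-value agrees with a permutation p-value on small groups", {
  set.seed(77)
  x <- rnorm(8)
  y <- rnorm(8, mean = 1)
  ref <- compareGroups(x, y)
  pool <- c(x, y)
  tStat <- function(a, b) {
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  }
  obs <- abs(tStat(x, y))
  hits <- replicate(1e4, {
    i <- sample(16, 8)
    abs(tStat(pool[i], pool[-i])) >= obs
  })
  expect_lt(abs(mean(hits) - ref$pValue), 0.03)
})

test_that("Pearson correlations and their t-distribution p-values match closed forms", {
  expect_equal(correlateNonants(1:9, 2 * (1:9))$r, 1)
  expect_equal(correlateNonants(1:9, -(1:9))$r, -1)

  ## r = 0.48 with n = 45 matched nonants is significant below 0.01
  pair <- corPair(45, 0.48, seed = 6)
  res <- correlateNonants(pair$x, pair$y)
  expect_equal(res$r, 0.48, tolerance = 1e-10)
  tHand <- 0.48 * sqrt((45 - 2) / (1 - 0.48^2))
  expect_equal(res$pValue, 2 * pt(-abs(tHand), df = 43), tolerance = 1e-10)
  expect_lt(res$pValue, 0.01)

  ## pairwise deletion of incomplete nonants
  xm <- c(1, 2, NA, 4, 5, 6); ym <- c(2, 4, 6, NA, 10, 12)
  expect_equal(correlateNonants(xm, ym)$n, 4L)
  expect_equal(correlateNonants(xm, ym)$r, 1)

  expect_error(correlateNonants(c(1, 2), c(1, 2)), "at least 3")
  expect_error(correlateNonants(rep(1, 5), 1:5), "variance")
})
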