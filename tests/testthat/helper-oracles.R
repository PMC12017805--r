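## Independent oracles used by the test suite. These deliberately take
## different routes than the package code they check.

## NNLS oracle via the finite KKT characterization: for each support
## set solve the unconstrained least-squares problem on that face and
## return the first solution satisfying primal feasibility (x >= 0)
## and dual feasibility (gradient <= 0 off the support).
nnlsKktOracle <- function(M, b, tol = 1e-9) {
  p <- ncol(M)
  for (code in 0:(2^p - 1L)) {
    S <- which(bitwAnd(code, bitwShiftL(1L, 0:(p - 1L))) > 0L)
    x <- rep(0, p)
    if (length(S)) {
      qrS <- qr(M[, S, drop = FALSE])
      if (qrS$rank < length(S)) next
      x[S] <- qr.coef(qrS, b)
    }
    if (any(x < -tol)) next
    w <- drop(crossprod(M, b - M %*% x))
    if (all(w[setdiff(seq_len(p), S)] <= tol)) return(pmax(x, 0))
  }
  stop("KKT enumeration found no solution")
}

## Brute-force local range: explicit double loop over pixels and
## window offsets with replicate padding, center included.
localRangeOracle <- function(img, window = 3L) {
  r <- window %/% 2L
  h <- nrow(img); w <- ncol(img)
  out <- matrix(NA_real_, h, w)
  for (y in seq_len(h))
    for (x in seq_len(w)) {
      if (is.na(img[y, x])) next
      vals <- c()
      for (dy in -r:r)
        for (dx in -r:r) {
          yy <- min(max(y + dy, 1L), h)
          xx <- min(max(x + dx, 1L), w)
          vals <- c(vals, img[yy, xx])
        }
      out[y, x] <- max(vals, na.rm = TRUE) - img[y, x]
    }
  out
}

## A pair of vectors whose sample Pearson correlation is exactly r:
## y is built from the standardized x plus an orthogonal residual.
corPair <- function(n, r, seed = 1L) {
  set.seed(seed)
  x <- stats::rnorm(n)
  u <- stats::rnorm(n)
  u <- stats::residuals(stats::lm(u ~ x))
  xs <- as.vector(scale(x))
  us <- as.vector(scale(u))
  list(x = xs, y = r * xs + sqrt(1 - r^2) * us)
}

## Standard 4x4 Beer-Lambert design used across tests.
testDesign <- function() {
  buildDesignMatrix(c(540, 560, 580, 610), defaultTongueBackground(),
                    builtinExtinctionTable())
}

## Homogeneous all-vessel scene with fixed chromophore products.
homogScene <- function(size, cHbO2, cHb)
  mpfm:::.homogeneousScene(size, cHbO2, cHb)
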