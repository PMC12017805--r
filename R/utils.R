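## Internal image / seeding helpers shared across modules.

## Integer-translate an image: output[y, x] = img[y - dy, x - dx],
## i.e. positive dy moves content down, positive dx moves it right.
## Exposed rows/cols outside the source are filled with `fill`.
shiftImage <- function(img, dy, dx, fill = NA_real_) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(fill, h, w)
  ys <- max(1L, 1L + dy):min(h, h + dy)
  xs <- max(1L, 1L + dx):min(w, w + dx)
  if (length(ys) && length(xs))
    out[ys, xs] <- img[ys - dy, xs - dx]
  out
}

## Replicate-pad an image by r pixels on every side.
padReplicate <- function(img, r) {
  ridx <- c(rep(1L, r), seq_len(nrow(img)), rep(nrow(img), r))
  cidx <- c(rep(1L, r), seq_len(ncol(img)), rep(ncol(img), r))
  img[ridx, cidx, drop = FALSE]
}

## Binary dilation with a (2r+1)^2 square structuring element,
## implemented as an OR over integer shifts (edge pixels see the
## in-image neighborhood only).
dilateMask <- function(mask, r = 1L) {
  if (r <= 0L) return(mask)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (dy in -r:r)
    for (dx in -r:r) {
      s <- shiftImage(mask * 1, dy, dx, fill = 0)
      out <- out | (s > 0)
    }
  out
}

## Derive a child seed from a base seed and a stream offset, keeping the
## result a valid 32-bit integer.
deriveSeed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + as.double(offset) * 104729) %%
               2147483629) + 1L
}

## Smooth random field on an h x w grid: white noise on a coarse
## n x n lattice, bilinearly interpolated up. Mean ~0, sd ~1.
smoothField <- function(h, w, coarse) {
  coarse <- max(2L, as.integer(coarse))
  z <- matrix(stats::rnorm(coarse * coarse), coarse, coarse)
  bilinearResize(z, h, w)
}

## Bilinear resize of a matrix to h x w.
bilinearResize <- function(z, h, w) {
  ch <- nrow(z); cw <- ncol(z)
  ys <- if (h == 1L) 1 else seq(1, ch, length.out = h)
  xs <- if (w == 1L) 1 else seq(1, cw, length.out = w)
  y0 <- pmin(floor(ys), ch - 1L); fy <- ys - y0
  x0 <- pmin(floor(xs), cw - 1L); fx <- xs - x0
  a <- z[cbind(rep(y0, w), rep(x0, each = h))]
  b <- z[cbind(rep(y0 + 1, w), rep(x0, each = h))]
  cc <- z[cbind(rep(y0, w), rep(x0 + 1, each = h))]
  d <- z[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))]
  fym <- rep(fy, w); fxm <- rep(fx, each = h)
  matrix((1 - fym) * (1 - fxm) * a + fym * (1 - fxm) * b +
           (1 - fym) * fxm * cc + fym * fxm * d, h, w)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Trapezoidal integral on an ordered grid.
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

`%||%` <- function(a, b) if (is.null(a)) b else a
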