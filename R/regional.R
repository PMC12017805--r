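## Regional (nonant) statistics: 3x3 partitioning, per-nonant means,
## global-max normalization, kernel density summaries, Student's
## t-tests and Pearson correlations between parameter pairs.

#' Partition an image into nine equal nonants
#'
#' Rows and columns are each split into three contiguous bands; the
#' first two bands have `floor(n/3)` pixels and the remainder goes to
#' the last band. Ranges are reported half-open and 0-based
#' (`row0 <= y < row1`), in row-major nonant order 0..8.
#'
#' @param height,width image size in pixels, >= 3 each.
#' @return Data frame with columns `nonant` (0..8), `row0`, `row1`,
#'   `col0`, `col1`.
#' @examples
#' nonantPartition(10, 10)
#' @export
nonantPartition <- function(height, width) {
  if (height < 3 || width < 3)
    stop("image must be at least 3 x 3 to partition into nonants")
  bands <- function(n) {
    b <- floor(n / 3)
    starts <- c(0L, b, 2L * b)
    ends <- c(b, 2L * b, n)
    cbind(starts, ends)
  }
  rb <- bands(as.integer(height)); cb <- bands(as.integer(width))
  idx <- expand.grid(col = 1:3, row = 1:3)   # row-major nonant order
  data.frame(nonant = 0:8,
             row0 = rb[idx$row, 1L], row1 = rb[idx$row, 2L],
             col0 = cb[idx$col, 1L], col1 = cb[idx$col, 2L])
}

#' Per-nonant means of a masked parameter map
#'
#' Mean over the valid pixels of each nonant: non-missing map pixels,
#' further restricted to `mask` when one is given (vessel pixels for
#' vascular maps, analysis-mask pixels for metabolic maps). Nonants
#' with no valid pixel get a missing mean.
#'
#' @param map numeric matrix (NA = missing).
#' @param mask optional logical matrix restricting the valid pixels.
#' @param partition partition from [nonantPartition()]; defaults to
#'   the map's own 3x3 partition.
#' @return Data frame with columns `nonant`, `mean`, `nValid`.
#' @export
nonantMeans <- function(map, mask = NULL, partition = NULL) {
  partition <- partition %||% nonantPartition(nrow(map), ncol(map))
  if (max(partition$row1) != nrow(map) || max(partition$col1) != ncol(map))
    stop("partition does not match the map size")
  use <- !is.na(map)
  if (!is.null(mask)) use <- use & (mask > 0)
  out <- partition["nonant"]
  out$mean <- NA_real_
  out$nValid <- 0L
  for (i in seq_len(nrow(partition))) {
    ys <- (partition$row0[i] + 1L):partition$row1[i]
    xs <- (partition$col0[i] + 1L):partition$col1[i]
    u <- use[ys, xs]
    out$nValid[i] <- sum(u)
    if (out$nValid[i] > 0L) out$mean[i] <- mean(map[ys, xs][u])
  }
  out
}

#' Normalize values by their global maximum
#'
#' Divides by the single highest value across all supplied values
#' (e.g. across both animal groups), so the normalized values peak at
#' 1. Intended for the THb indicator and the metabolic endpoint
#' intensities; StO2, already a fraction, is never normalized.
#'
#' @param values numeric vector (NAs allowed).
#' @return `values / max(values)`, with attribute `"globalMax"`.
#' @export
normalizeGlobalMax <- function(values) {
  m <- max(values, na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop("global maximum must be positive")
  out <- values / m
  attr(out, "globalMax") <- m
  out
}

#' Kernel density summary of pixel values
#'
#' Gaussian kernel density estimate with Silverman's rule-of-thumb
#' bandwidth on a 256-point grid spanning `[min - 3h, max + 3h]`, plus
#' the sample mean (the dashed-line marker convention of the
#' distribution figures).
#'
#' @param values numeric vector; at least 10 finite values, not all
#'   equal.
#' @param bandwidth optional fixed bandwidth; default Silverman
#'   (`stats::bw.nrd0`).
#' @param n grid length, default 256.
#' @return Data frame of class `density_curve` with columns `grid` and
#'   `density`; attributes `bandwidth` and `mean`.
#' @export
kdeDistribution <- function(values, bandwidth = NULL, n = 256L) {
  values <- values[is.finite(values)]
  if (length(values) < 10L)
    stop("need at least 10 finite values for a density estimate")
  if (max(values) == min(values))
    stop("all values are equal; a density estimate is degenerate ",
         "(use a histogram or report the constant)")
  h <- bandwidth %||% stats::bw.nrd0(values)
  d <- stats::density(values, bw = h, kernel = "gaussian", n = n,
                      from = min(values) - 3 * h,
                      to = max(values) + 3 * h)
  out <- data.frame(grid = d$x, density = d$y)
  attr(out, "bandwidth") <- h
  attr(out, "mean") <- mean(values)
  class(out) <- c("density_curve", "data.frame")
  out
}

#' Compare a parameter between groups with Student's t-test
#'
#' Two-sample Student's t-test (equal variances pooled, per the
#' analysis convention; Welch available via `varEqual = FALSE`) on the
#' nonant means of the two groups, two-sided.
#'
#' @param normalValues,tumorValues numeric vectors of nonant means
#'   (9 per animal); NAs dropped.
#' @param varEqual pool variances (Student) or not (Welch).
#' @return List with `statistic` (t), `pValue`, `meanNormal`,
#'   `meanTumor`, `df`, `nNormal`, `nTumor`.
#' @examples
#' compareGroups(c(1, 2, 3), c(4, 5, 6))
#' @export
compareGroups <- function(normalValues, tumorValues, varEqual = TRUE) {
  x <- normalValues[!is.na(normalValues)]
  y <- tumorValues[!is.na(tumorValues)]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 non-missing values per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y))
    return(list(statistic = 0, pValue = 1, meanNormal = mean(x),
                meanTumor = mean(y), df = length(x) + length(y) - 2,
                nNormal = length(x), nTumor = length(y)))
  tt <- stats::t.test(x, y, var.equal = varEqual)
  list(statistic = unname(tt$statistic), pValue = tt$p.value,
       meanNormal = mean(x), meanTumor = mean(y),
       df = unname(tt$parameter), nNormal = length(x),
       nTumor = length(y))
}

#' Pearson correlation between two parameters over matched nonants
#'
#' Pearson's r with the two-sided t-distribution p-value on n - 2
#' degrees of freedom; nonants missing in either vector are dropped
#' pairwise.
#'
#' @param x,y numeric vectors of matched nonant means.
#' @return List with `r`, `pValue`, `n`.
#' @examples
#' correlateNonants(1:9, (1:9) * 2)
#' @export
correlateNonants <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("need at least 3 complete nonant pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the vectors")
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), pValue = ct$p.value, n = length(x))
}
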