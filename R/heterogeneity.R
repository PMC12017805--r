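## Spatial metabolic heterogeneity: local-range texture maps and the
## four-group 2-NBDG x TMRE intensity clustering.

#' Local range variation map
#'
#' Per-pixel heterogeneity statistic: the difference between the
#' maximum over a sliding `window x window` neighborhood (center pixel
#' included, replicate-padded borders) and the center pixel value. The
#' statistic is non-negative and zero wherever the center attains the
#' neighborhood maximum; larger values mark locally rougher intensity.
#' Missing center pixels propagate as missing; missing neighbors are
#' ignored in the neighborhood maximum.
#'
#' @param image numeric matrix (NA = missing).
#' @param window odd window size >= 3, default 3 (the smallest, most
#'   sensitive window).
#' @param semantics `"max-minus-center"` (default: neighborhood
#'   maximum minus the center value) or `"max-minus-min"` (classical
#'   range filter: neighborhood maximum minus minimum).
#' @return List of class `local_range_map` with elements `image` (the
#'   per-pixel local range values), `window`, `semantics` and `border`
#'   (always `"replicate"`).
#' @examples
#' localRangeMap(matrix(c(1, 2, 3, 9), 2))$image
#' @export
localRangeMap <- function(image, window = 3L,
                          semantics = c("max-minus-center",
                                        "max-minus-min")) {
  semantics <- match.arg(semantics)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 3")
  if (window > min(dim(image)))
    stop("'window' exceeds the image size")
  r <- window %/% 2L
  h <- nrow(image); w <- ncol(image)
  pad <- padReplicate(image, r)
  mx <- matrix(-Inf, h, w)
  mn <- matrix(Inf, h, w)
  for (dy in 0:(window - 1L))
    for (dx in 0:(window - 1L)) {
      nb <- pad[dy + seq_len(h), dx + seq_len(w)]
      mx <- pmax(mx, nb, na.rm = TRUE)
      mn <- pmin(mn, nb, na.rm = TRUE)
    }
  out <- if (semantics == "max-minus-center") mx - image else {
    d <- mx - mn
    d[is.na(image)] <- NA_real_   # missing centers still propagate
    d
  }
  out[is.infinite(mx) & !is.na(image)] <- NA_real_  # all-NA neighborhood
  structure(list(image = out, window = window, semantics = semantics,
                 border = "replicate"),
            class = "local_range_map")
}

#' Binarize an endpoint map against its global mean
#'
#' A pixel is "high" when its intensity strictly exceeds the global
#' mean intensity over this animal's analysis mask; ties and lower
#' values are "low". Missing pixels are excluded from the mean and
#' stay missing in the output.
#'
#' @param endpoint an [EndpointMap-class], or a numeric matrix.
#' @return Logical matrix (TRUE = high, NA = missing) with the global
#'   mean attached as attribute `"globalMean"`.
#' @export
binarizeByGlobalMean <- function(endpoint) {
  img <- if (is(endpoint, "EndpointMap")) endpoint@image else endpoint
  if (!any(is.finite(img)))
    stop("endpoint map has no finite pixels")
  m <- mean(img, na.rm = TRUE)
  out <- img > m
  attr(out, "globalMean") <- m
  out
}

#' Merge probe binarizations into the four-group cluster map
#'
#' Codes: 1 = low 2-NBDG / low TMRE, 2 = low 2-NBDG / high TMRE,
#' 3 = high 2-NBDG / low TMRE, 4 = high 2-NBDG / high TMRE. Codes are
#' defined exactly on the pixels valid in both inputs.
#'
#' @param nbdgBinary,tmreBinary logical matrices from
#'   [binarizeByGlobalMean()], same shape.
#' @return List of class `cluster_map` with `codes` (integer matrix in
#'   1..4, NA = missing) and `thresholds` (the two global means, when
#'   available on the inputs).
#' @export
mergeClusters <- function(nbdgBinary, tmreBinary) {
  if (!identical(dim(nbdgBinary), dim(tmreBinary)))
    stop("binarized maps must have the same shape")
  codes <- 1L + 2L * (nbdgBinary == TRUE) + 1L * (tmreBinary == TRUE)
  codes[is.na(nbdgBinary) | is.na(tmreBinary)] <- NA_integer_
  mode(codes) <- "integer"
  structure(list(
    codes = codes,
    thresholds = c(nbdg = attr(nbdgBinary, "globalMean") %||% NA_real_,
                   tmre = attr(tmreBinary, "globalMean") %||% NA_real_)),
    class = "cluster_map")
}

#' Pixel counts per metabolic cluster
#'
#' @param map a `cluster_map` from [mergeClusters()].
#' @return Data frame with columns `code` (1..4) and `count`; missing
#'   pixels are excluded, so the counts sum to the number of jointly
#'   valid pixels.
#' @export
clusterCounts <- function(map) {
  codes <- if (inherits(map, "cluster_map")) map$codes else map
  data.frame(code = 1:4,
             count = vapply(1:4,
                            function(k) sum(codes == k, na.rm = TRUE),
                            0L))
}
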