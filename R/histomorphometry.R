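#' Otsu's automatic threshold
#'
#' Deterministic histogram threshold maximizing between-class variance; the
#' reproducible stand-in for the manual histogram adjustment used in classic
#' section histomorphometry.
#'
#' @param x Numeric values (image intensities).
#' @param nbins Histogram bins.
#' @return Threshold value (a bin edge on the intensity scale).
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (!(rng[2] > rng[1]))
    stop("constant image: no bimodality to threshold", call. = FALSE)
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(pmin(nbins, findInterval(x, br, all.inside = TRUE)), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  valid <- w0 > 0 & w0 < 1
  bc <- rep(-Inf, nbins)
  bc[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * (1 - w0[valid]))
  k <- which.max(bc)
  br[k + 1L]  # upper edge of the best split bin
}

#' Mineralized area fraction of a histology section
#'
#' Binarizes a grayscale section (dark = normally mineralized dentin, bright =
#' unmineralized/interglobular defect) and reports the percentage of
#' mineralized-class pixels over the total; `100 - result` is the
#' interglobular defect area percentage.
#'
#' @param section Numeric matrix (grayscale image) or the result of
#'   [generate_histology_section()].
#' @param threshold `"auto"` ([otsu_threshold()]) or a numeric cutoff.
#' @param dark_is_mineralized If `TRUE` (default), pixels at or below the
#'   threshold count as mineralized.
#' @return Percent mineralized area (0-100).
#' @export
mineralized_area_fraction <- function(section, threshold = "auto",
                                      dark_is_mineralized = TRUE) {
  img <- if (is.list(section)) section$image else section
  if (length(img) == 0L) stop("empty image", call. = FALSE)
  thr <- if (identical(threshold, "auto")) otsu_threshold(img)
         else as.numeric(threshold)
  frac <- if (dark_is_mineralized) mean(img <= thr) else mean(img > thr)
  100 * frac
}

#' Mean thickness of a band-shaped 2-D layer
#'
#' For a band (predentin, cementum) bounded by two opposing surfaces, the
#' per-pixel thickness is the sum of the Euclidean distances to the two
#' adjacent complement regions minus one pixel (centre-to-centre distances
#' overshoot the band width by exactly one pixel on a straight band); the
#' layer thickness is its mean over the band, scaled by `um_per_px`.
#'
#' @param mask Logical matrix marking the band.
#' @param um_per_px Pixel pitch.
#' @return Mean thickness, micrometres.
#' @export
layer_thickness_2d <- function(mask, um_per_px) {
  m <- vol_data(mask)
  if (!any(m)) stop("band mask is empty", call. = FALSE)
  comp <- label_components(!m)
  border <- dilate6(m) & !m
  adj <- setdiff(unique(comp[border]), 0L)
  if (length(adj) != 2L)
    stop("mask is not band-like: expected exactly two opposing boundary regions, found ",
         length(adj), call. = FALSE)
  dA <- sqrt(feature_sqedt(comp == adj[1]))
  dB <- sqrt(feature_sqedt(comp == adj[2]))
  mean(dA[m] + dB[m] - 1) * um_per_px
}

#' Average replicate sections per tooth
#'
#' Histomorphometric endpoints are measured on replicate sections (typically
#' n = 3 per tooth) and averaged per tooth before cohort statistics.
#'
#' @param data A `data.frame` with columns `tooth` and `value`, or a numeric
#'   vector of replicates for a single tooth.
#' @return For a data frame, a `data.frame(tooth, value)` of per-tooth means;
#'   for a vector, the mean.
#' @export
section_replicate_summary <- function(data) {
  if (is.numeric(data)) {
    if (length(data) < 1L) stop("no replicates", call. = FALSE)
    return(mean(data))
  }
  stopifnot(is.data.frame(data), all(c("tooth", "value") %in% names(data)))
  out <- aggregate(value ~ tooth, data = data, FUN = mean)
  out[order(out$tooth), , drop = FALSE]
}
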