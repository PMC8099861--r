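#' Select pulmonary parenchyma by HU thresholding within a lung mask
#'
#' Restricts a lung mask to pixels whose CT number falls in the parenchymal
#' window (default -1024 to -242 HU, the aerated-lung range used for texture
#' analysis). Pixels outside the selection are treated as background by all
#' downstream texture operations.
#'
#' @param slice a [ct_slice()].
#' @param mask a [lung_mask()] matching the slice dimensions.
#' @param lo,hi closed HU window bounds.
#' @return A `parenchyma_region`: list with `selected` (logical matrix) and
#'   `hu_window`.
#' @export
threshold_parenchyma <- function(slice, mask, lo = -1024, hi = -242) {
  stopifnot(inherits(slice, "ct_slice"), inherits(mask, "lung_mask"))
  check_same_dim(slice, mask$mask)
  if (lo >= hi) stop("threshold_parenchyma: lo must be < hi")
  selected <- mask$mask & slice$pixels >= lo & slice$pixels <= hi
  if (!any(selected))
    stop("threshold_parenchyma: no lung pixels fall in the HU window [",
         lo, ", ", hi, "]")
  structure(list(selected = selected, hu_window = c(lo, hi)),
            class = "parenchyma_region")
}

#' Subpleural band of a lung mask
#'
#' Returns the peripheral rim of the lung: lung pixels whose Euclidean
#' distance to the nearest non-lung pixel is at most `depth_px`. This is the
#' deterministic, mask-derived replacement for a manual brush selection of
#' the subpleural region.
#'
#' @param mask a [lung_mask()].
#' @param depth_px band depth in pixels (>= 1).
#' @return A [lung_mask()] whose mask is the band (subset of the input).
#' @export
subpleural_band <- function(mask, depth_px = 10) {
  stopifnot(inherits(mask, "lung_mask"), depth_px >= 1)
  d <- EBImage::distmap(mask$mask * 1)
  band <- mask$mask & (d <= depth_px)
  if (all(band == mask$mask)) {
    warning("subpleural_band: lung is nowhere thicker than depth_px; ",
            "the whole lung is subpleural")
    band <- mask$mask
  }
  lung_mask(band, mask$lung_label)
}

#' First-order statistics of a masked CT region
#'
#' Area, mean, SD, CV, min, max, skewness and excess kurtosis of the HU
#' values inside a region. SD uses the n-1 denominator; skewness and
#' kurtosis use population central moments (kurtosis reported as excess,
#' i.e. 0 for a normal distribution).
#'
#' @param slice a [ct_slice()].
#' @param region a `parenchyma_region` or [lung_mask()].
#' @return A one-row data.frame with columns `n_px`, `area_mm2`, `hu_mean`,
#'   `hu_sd`, `hu_cv`, `hu_min`, `hu_max`, `skewness`, `kurtosis_excess`.
#'   Undefined statistics (n < 2, or zero variance for the shape moments)
#'   are `NA`.
#' @export
first_order_stats <- function(slice, region) {
  stopifnot(inherits(slice, "ct_slice"))
  sel <- region_selected(region)
  check_same_dim(slice, sel)
  x <- slice$pixels[sel]
  n <- length(x)
  if (n < 1L) stop("first_order_stats: empty region")
  area <- n * prod(slice$pixel_spacing_mm)
  mu <- mean(x)
  out <- data.frame(
    n_px = n, area_mm2 = area, hu_mean = mu,
    hu_sd = NA_real_, hu_cv = NA_real_,
    hu_min = min(x), hu_max = max(x),
    skewness = NA_real_, kurtosis_excess = NA_real_)
  if (n >= 2L) {
    out$hu_sd <- stats::sd(x)
    out$hu_cv <- out$hu_sd / mu
    m2 <- mean((x - mu)^2)
    if (m2 > 0) {
      out$skewness <- mean((x - mu)^3) / m2^1.5
      out$kurtosis_excess <- mean((x - mu)^4) / m2^2 - 3
    }
  }
  out
}
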