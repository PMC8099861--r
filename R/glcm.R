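#' Quantize region HU values to discrete grey levels
#'
#' Linear binning of the interval `[lo, hi]` into `n_levels` equal-width
#' bins, producing integer levels 1..n_levels; out-of-range values are
#' clamped to the end bins. Background pixels (outside the region) carry
#' `NA` and never enter co-occurrence matrices.
#'
#' @param slice a [ct_slice()].
#' @param region a `parenchyma_region` or [lung_mask()].
#' @param n_levels number of grey levels (default 64).
#' @param grey_limits either `"auto"` (observed min/max of the selected
#'   region) or a numeric `c(lo, hi)` such as `c(-1024, -242)`.
#' @return Integer matrix of levels with `NA` background; attributes
#'   `n_levels` and `grey_limits` record the quantization actually used.
#' @export
quantize_levels <- function(slice, region, n_levels = 64,
                            grey_limits = "auto") {
  stopifnot(inherits(slice, "ct_slice"), n_levels >= 2)
  sel <- region_selected(region)
  check_same_dim(slice, sel)
  x <- slice$pixels[sel]
  if (identical(grey_limits, "auto")) {
    lims <- range(x)
  } else {
    lims <- as.numeric(grey_limits)
    if (length(lims) != 2L || lims[1] > lims[2])
      stop("quantize_levels: grey_limits must be 'auto' or c(lo, hi) with lo < hi")
  }
  lev <- matrix(NA_integer_, nrow(sel), ncol(sel))
  if (lims[1] == lims[2]) {
    warning("quantize_levels: degenerate grey limits (lo == hi); ",
            "all region pixels assigned level 1")
    lev[sel] <- 1L
  } else {
    raw <- floor((x - lims[1]) / (lims[2] - lims[1]) * n_levels) + 1
    lev[sel] <- as.integer(pmin(pmax(raw, 1), n_levels))
  }
  attr(lev, "n_levels") <- as.integer(n_levels)
  attr(lev, "grey_limits") <- lims
  lev
}

# (row, col) pixel offsets for the four standard GLCM directions, with image
# rows increasing downward.
glcm_offset <- function(direction_deg) {
  switch(as.character(direction_deg),
         "0"   = c(0L, 1L),
         "45"  = c(-1L, 1L),
         "90"  = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stop("direction_deg must be one of 0, 45, 90, 135"))
}

#' Grey-level co-occurrence matrix of a quantized image
#'
#' Counts co-occurrences of grey-level pairs at a one-pixel offset in the
#' given direction. A pair contributes only when both pixels are inside the
#' region (non-`NA`). The symmetric GLCM adds the transpose, so it is
#' symmetric across its diagonal by construction; normalization divides by
#' the total pair count.
#'
#' @param levels quantized level image from [quantize_levels()].
#' @param direction_deg one of 0, 45, 90, 135 (degrees).
#' @param symmetric add the transposed counts (default `TRUE`).
#' @param normalize divide by the total count so entries sum to 1.
#' @return A `glcm` object: list with `matrix` (n_levels x n_levels),
#'   `direction_deg`, `normalized`, `n_levels`, `grey_limits`.
#' @export
compute_glcm <- function(levels, direction_deg, symmetric = TRUE,
                         normalize = TRUE) {
  n <- attr(levels, "n_levels")
  if (is.null(n)) n <- max(levels, na.rm = TRUE)
  off <- glcm_offset(direction_deg)
  nr <- nrow(levels); nc <- ncol(levels)
  r0 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c0 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  a <- levels[r0, c0, drop = FALSE]
  b <- levels[r0 + off[1], c0 + off[2], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok))
    stop("compute_glcm: no valid pixel pairs for direction ", direction_deg)
  counts <- matrix(tabulate((a[ok] - 1L) * n + b[ok], nbins = n * n),
                   nrow = n, ncol = n, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  m <- if (normalize) counts / sum(counts) else counts
  structure(list(matrix = m, direction_deg = direction_deg,
                 normalized = normalize, n_levels = n,
                 grey_limits = attr(levels, "grey_limits")),
            class = "glcm")
}

# Haralick-type statistics of one normalized GLCM. correlation is NA when
# either marginal variance is zero (e.g. a constant image).
glcm_stats_one <- function(p) {
  n <- nrow(p)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  mu_i <- sum(seq_len(n) * pi_)
  mu_j <- sum(seq_len(n) * pj_)
  var_i <- sum((seq_len(n) - mu_i)^2 * pi_)
  var_j <- sum((seq_len(n) - mu_j)^2 * pj_)
  corr <- if (var_i > 0 && var_j > 0)
    sum(p * (i - mu_i) * (j - mu_j)) / sqrt(var_i * var_j) else NA_real_
  c(homogeneity = sum(p / (1 + abs(i - j))),
    contrast = sum(p * (i - j)^2),
    energy = sum(p^2),
    correlation = corr)
}

#' Shannon entropy of an equal-width intensity histogram
#'
#' Entropy in bits, `-sum(p_i * log2(p_i))`, of the histogram of `x` over
#' `n_bins` equal-width bins spanning its observed range; `0*log(0)` terms
#' are dropped. A constant sample has entropy 0; a sample uniform over the
#' bins has entropy `log2(n_bins)`.
#'
#' @param x numeric values (e.g. region HU values).
#' @param n_bins number of histogram bins (default 256).
#' @return Entropy in bits.
#' @export
histogram_entropy <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("histogram_entropy: no finite values")
  lo <- min(x); hi <- max(x)
  if (lo == hi) return(0)
  bin <- pmin(floor((x - lo) / (hi - lo) * n_bins) + 1, n_bins)
  p <- tabulate(bin, nbins = n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Texture statistics averaged over the four GLCM directions
#'
#' Computes homogeneity, contrast, energy and correlation from each of the
#' four directional GLCMs and averages the statistics (not the matrices)
#' across directions. Entropy is computed separately, from an equal-width
#' histogram of the region's HU values, not from the GLCM. Directions whose
#' correlation is undefined (zero marginal variance) are excluded from the
#' correlation average with a warning.
#'
#' @param glcms list of four normalized `glcm` objects (directions 0, 45,
#'   90, 135).
#' @param hu_values numeric vector of the region's HU values (for entropy);
#'   may be `NULL` to skip entropy.
#' @param n_bins_entropy histogram bin count for entropy (default 256).
#' @return One-row data.frame: `homogeneity`, `contrast`, `energy`,
#'   `correlation`, `entropy_bits`.
#' @export
glcm_features <- function(glcms, hu_values = NULL, n_bins_entropy = 256) {
  stopifnot(length(glcms) >= 1L)
  for (g in glcms) {
    stopifnot(inherits(g, "glcm"))
    if (!g$normalized) stop("glcm_features: all GLCMs must be normalized")
  }
  per_dir <- vapply(glcms, function(g) glcm_stats_one(g$matrix), numeric(4))
  corr <- per_dir["correlation", ]
  if (anyNA(corr)) {
    warning("glcm_features: correlation undefined in ", sum(is.na(corr)),
            " direction(s); excluded from the average")
  }
  data.frame(
    homogeneity = mean(per_dir["homogeneity", ]),
    contrast = mean(per_dir["contrast", ]),
    energy = mean(per_dir["energy", ]),
    correlation = if (all(is.na(corr))) NA_real_ else mean(corr, na.rm = TRUE),
    entropy_bits = if (is.null(hu_values)) NA_real_ else
      histogram_entropy(hu_values, n_bins_entropy))
}

#' Full CT texture analysis of one masked lung
#'
#' Convenience wrapper: thresholds parenchyma, quantizes to `n_levels`,
#' builds the four symmetric normalized directional GLCMs and returns the
#' direction-averaged texture statistics plus histogram entropy.
#'
#' @inheritParams threshold_parenchyma
#' @inheritParams quantize_levels
#' @param n_bins_entropy histogram bin count for entropy.
#' @return One-row data.frame as [glcm_features()], plus quantization
#'   metadata columns `n_levels`, `grey_lo`, `grey_hi`.
#' @export
ct_texture <- function(slice, mask, lo = -1024, hi = -242, n_levels = 64,
                       grey_limits = "auto", n_bins_entropy = 256) {
  region <- threshold_parenchyma(slice, mask, lo, hi)
  lev <- quantize_levels(slice, region, n_levels, grey_limits)
  glcms <- lapply(c(0, 45, 90, 135), function(d) compute_glcm(lev, d))
  feats <- glcm_features(glcms, hu_values = slice$pixels[region$selected],
                         n_bins_entropy = n_bins_entropy)
  lims <- attr(lev, "grey_limits")
  cbind(feats, data.frame(n_levels = n_levels,
                          grey_lo = lims[1], grey_hi = lims[2]))
}
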