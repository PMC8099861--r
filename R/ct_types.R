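#' CT slice with Hounsfield-unit pixels and spacing metadata
#'
#' Bundles a 2-D matrix of calibrated CT numbers (Hounsfield units, HU) with
#' its in-plane pixel spacing and study identifiers. HU are validated against
#' the physically plausible range for clinical CT (-1100 to 3100).
#'
#' @param pixels numeric matrix of HU values, at least 2x2.
#' @param pixel_spacing_mm numeric length-2, (row_mm, col_mm), both > 0.
#' @param sheep_id subject identifier.
#' @param timepoint_days integer study day (negative = before irradiation).
#' @param slice_id slice identifier within the study.
#' @return An object of class `ct_slice`.
#' @export
ct_slice <- function(pixels, pixel_spacing_mm = c(1, 1), sheep_id = NA,
                     timepoint_days = NA_integer_, slice_id = NA) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("ct_slice: pixels must be at least 2x2")
  rng <- range(pixels, na.rm = TRUE)
  if (rng[1] < -1100 || rng[2] > 3100)
    stop("ct_slice: HU values outside the plausible range [-1100, 3100]")
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0))
    stop("ct_slice: pixel_spacing_mm must be two positive numbers")
  structure(
    list(pixels = pixels, pixel_spacing_mm = pixel_spacing_mm,
         sheep_id = sheep_id, timepoint_days = as.integer(timepoint_days),
         slice_id = slice_id),
    class = "ct_slice")
}

#' Binary lung mask paired with a CT slice
#'
#' @param mask logical matrix, same dimensions as the slice it describes;
#'   `TRUE` marks lung.
#' @param lung_label `"Rx"` (radio-exposed) or `"CON"` (contralateral
#'   control).
#' @return An object of class `lung_mask`.
#' @export
lung_mask <- function(mask, lung_label = c("Rx", "CON")) {
  lung_label <- match.arg(lung_label)
  mask <- as.matrix(mask)
  if (!is.logical(mask)) mask <- mask != 0
  if (!any(mask)) stop("lung_mask: mask has no lung pixels")
  structure(list(mask = mask, lung_label = lung_label), class = "lung_mask")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("ct_slice %s (sheep %s, day %s): %d x %d px, %.3g x %.3g mm, HU [%g, %g]\n",
              as.character(x$slice_id), as.character(x$sheep_id),
              as.character(x$timepoint_days), nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf("lung_mask [%s]: %d x %d px, %d lung pixels\n", x$lung_label,
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

# Accept either a lung_mask or a parenchyma_region wherever a pixel
# selection is needed.
region_selected <- function(region) {
  if (inherits(region, "parenchyma_region")) return(region$selected)
  if (inherits(region, "lung_mask")) return(region$mask)
  if (is.matrix(region) && is.logical(region)) return(region)
  stop("expected a parenchyma_region, lung_mask, or logical matrix")
}

check_same_dim <- function(slice, mask) {
  if (!identical(dim(slice$pixels), dim(mask)))
    stop("mask dimensions do not match the CT slice")
  invisible(TRUE)
}
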