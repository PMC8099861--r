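# Plain-file readers/writers: 16-bit TIFF CT slices with a JSON sidecar for
# spacing and HU calibration, single-channel PNG/TIFF lung masks, and CSV
# study tables.

#' Read a CT slice from a 16-bit TIFF plus JSON sidecar
#'
#' The TIFF stores unsigned integers; the sidecar supplies the linear HU
#' calibration (`hu = rescale_slope * stored + rescale_intercept`), the
#' pixel spacing, and identifiers. By default the sidecar is
#' `<path>.json`.
#'
#' @param path TIFF file path.
#' @param sidecar JSON sidecar path (default `paste0(path, ".json")`).
#' @return A [ct_slice()].
#' @export
read_ct_slice <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(sidecar))
    stop("read_ct_slice: sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  stored <- tiff::readTIFF(path, as.is = TRUE)
  slope <- meta$rescale_slope %||% 1
  intercept <- meta$rescale_intercept %||% 0
  ct_slice(stored * slope + intercept,
           pixel_spacing_mm = as.numeric(meta$pixel_spacing_mm),
           sheep_id = meta$sheep_id %||% NA,
           timepoint_days = meta$timepoint_days %||% NA_integer_,
           slice_id = meta$slice_id %||% basename(path))
}

#' Write a CT slice as 16-bit TIFF plus JSON sidecar
#'
#' HU values are stored with a +1024 intercept so the full parenchymal
#' range maps onto unsigned 16-bit integers.
#'
#' @param slice a [ct_slice()].
#' @param path output TIFF path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_ct_slice <- function(slice, path) {
  stopifnot(inherits(slice, "ct_slice"))
  stored <- round(slice$pixels + 1024)
  tiff::writeTIFF(stored / 65535, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_spacing_mm = slice$pixel_spacing_mm,
         rescale_slope = 1,
         rescale_intercept = -1024,
         sheep_id = slice$sheep_id, timepoint_days = slice$timepoint_days,
         slice_id = slice$slice_id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a lung mask from a single-channel PNG or TIFF
#'
#' Nonzero pixels are lung.
#'
#' @param path image path (`.png`, `.tif`/`.tiff`).
#' @param lung_label `"Rx"` or `"CON"`.
#' @return A [lung_mask()].
#' @export
read_lung_mask <- function(path, lung_label = c("Rx", "CON")) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("read_lung_mask: unsupported format '", ext, "'"))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  lung_mask(img > 0, match.arg(lung_label))
}

#' Read / write long-format study tables as CSV
#'
#' @param path CSV path.
#' @return [read_study_table()]: a validated [study_table()].
#' @export
read_study_table <- function(path) {
  study_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_study_table
#' @param table data.frame to write.
#' @export
write_study_table <- function(table, path) {
  utils::write.csv(study_table(table), path, row.names = FALSE)
  invisible(path)
}
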