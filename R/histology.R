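#' Brightfield histology field
#'
#' An 8-bit RGB field image with physical calibration and study metadata.
#'
#' @param pixels H x W x 3 array, values 0-255.
#' @param microns_per_pixel physical pixel size, um (> 0).
#' @param field_id,sheep_id,lung_label,stain_name identifiers; `stain_name`
#'   is one of `"PicrosiriusRed"`, `"ASMA-DAB"`, `"CD31-DAB"`,
#'   `"DCLAMP-DAB"`, `"Ki67-DAB"`.
#' @return An object of class `rgb_field`.
#' @export
rgb_field <- function(pixels, microns_per_pixel, field_id = NA, sheep_id = NA,
                      lung_label = NA, stain_name = NA) {
  pixels <- as.array(pixels)
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("rgb_field: pixels must be an H x W x 3 array")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("rgb_field: channel values must lie in [0, 255]")
  if (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0)
    stop("rgb_field: microns_per_pixel must be > 0")
  known <- c("PicrosiriusRed", "ASMA-DAB", "CD31-DAB", "DCLAMP-DAB",
             "Ki67-DAB")
  if (!is.na(stain_name) && !stain_name %in% known)
    stop("rgb_field: unknown stain_name '", stain_name, "'")
  structure(list(pixels = pixels, microns_per_pixel = microns_per_pixel,
                 field_id = field_id, sheep_id = sheep_id,
                 lung_label = lung_label, stain_name = stain_name),
            class = "rgb_field")
}

#' Stain optical-density vector matrices
#'
#' A stain-vector matrix has one unit-norm row per stain: the relative
#' optical densities of that stain in the R, G and B channels. The bundled
#' sets are the classical haematoxylin + DAB pair (for immunostains) and a
#' red-dominant vector for Picrosirius Red with a haematoxylin counterstain;
#' both complete the third row with the normalized cross product so the
#' matrix is invertible. Vectors can also be calibrated from a pure-stain
#' image with [calibrate_stain_vector()].
#'
#' @param rows named list or matrix of 2 or 3 stain vectors (rows).
#' @return A `stain_vectors` object: 3 x 3 matrix, unit rows, with stain
#'   names as rownames.
#' @export
stain_vectors <- function(rows) {
  m <- if (is.matrix(rows)) rows else do.call(rbind, rows)
  if (ncol(m) != 3L || !nrow(m) %in% c(2L, 3L))
    stop("stain_vectors: need 2 or 3 rows of RGB optical densities")
  m <- m / sqrt(rowSums(m^2))
  if (nrow(m) == 2L) {
    v3 <- c(m[1, 2] * m[2, 3] - m[1, 3] * m[2, 2],
            m[1, 3] * m[2, 1] - m[1, 1] * m[2, 3],
            m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
    if (sqrt(sum(v3^2)) < 1e-8)
      stop("stain_vectors: the two stain vectors are collinear")
    m <- rbind(m, v3 / sqrt(sum(v3^2)))
    rownames(m)[3] <- "residual"
  }
  if (kappa(m) > 1e6) stop("stain_vectors: matrix is ill-conditioned")
  structure(m, class = c("stain_vectors", "matrix"))
}

#' @rdname stain_vectors
#' @export
stain_vectors_hdab <- function() {
  stain_vectors(list(haematoxylin = c(0.650, 0.704, 0.286),
                     dab = c(0.268, 0.570, 0.776)))
}

#' @rdname stain_vectors
#' @export
stain_vectors_psr <- function() {
  # Picrosirius Red absorbs strongly in green/blue; haematoxylin counterstain.
  stain_vectors(list(picrosirius = c(0.148, 0.772, 0.618),
                     haematoxylin = c(0.650, 0.704, 0.286)))
}

#' Calibrate one stain vector from a pure-stain image
#'
#' Estimates a stain's optical-density direction as the mean OD vector over
#' pixels with appreciable absorbance, normalized to unit length.
#'
#' @param field an [rgb_field()] of a pure-stain control.
#' @param background per-channel background intensity (default 255).
#' @param min_od pixels with total OD below this are ignored.
#' @return Unit-norm numeric length-3 vector.
#' @export
calibrate_stain_vector <- function(field, background = c(255, 255, 255),
                                   min_od = 0.05) {
  od <- rgb_to_od(field, background)
  tot <- od[, , 1] + od[, , 2] + od[, , 3]
  keep <- tot > min_od
  if (!any(keep)) stop("calibrate_stain_vector: image has no absorbing pixels")
  v <- c(mean(od[, , 1][keep]), mean(od[, , 2][keep]), mean(od[, , 3][keep]))
  v / sqrt(sum(v^2))
}

#' RGB to optical density (Beer-Lambert)
#'
#' `OD_c = -log10((I_c + 1) / background_c)`, clipped to be nonnegative.
#' The +1 offset keeps fully absorbing pixels finite.
#'
#' @param field an [rgb_field()].
#' @param background per-channel background (white) intensity.
#' @return H x W x 3 array of optical densities.
#' @export
rgb_to_od <- function(field, background = c(255, 255, 255)) {
  stopifnot(inherits(field, "rgb_field"), all(background > 0))
  background <- rep_len(background, 3L)
  od <- field$pixels
  for (c in 1:3) od[, , c] <- -log10((field$pixels[, , c] + 1) / background[c])
  od[od < 0] <- 0
  od
}

#' Unmix an optical-density image into per-stain concentration maps
#'
#' Solves the linear Beer-Lambert mixing model per pixel: the observed OD
#' vector is the concentration-weighted sum of the stain vectors, so
#' concentrations are recovered with the inverse stain matrix. Negative
#' concentrations (noise) are clipped to zero.
#'
#' @param od H x W x 3 OD array from [rgb_to_od()].
#' @param vectors a [stain_vectors()] matrix.
#' @return Named list of H x W concentration matrices, one per stain.
#' @export
unmix_stains <- function(od, vectors) {
  stopifnot(inherits(vectors, "stain_vectors"))
  d <- dim(od)
  O <- matrix(od, ncol = 3L)           # pixels x channels
  C <- O %*% solve(unclass(vectors))   # pixels x stains
  C[C < 0] <- 0
  out <- lapply(seq_len(ncol(C)), function(k) matrix(C[, k], d[1], d[2]))
  names(out) <- rownames(vectors)
  out
}

#' Tissue mask and tissue area of a histology field
#'
#' A pixel is tissue if it is not background-white: brightness (HSV value,
#' 0-255) below `brightness_max` or saturation above `saturation_min`.
#'
#' @param field an [rgb_field()].
#' @param brightness_max brightness cutoff (default 230).
#' @param saturation_min saturation cutoff (default 0.04).
#' @return List: `mask` (logical), `tissue_area_mm2`, `valid` (`FALSE` when
#'   no tissue pixel was found).
#' @export
tissue_mask <- function(field, brightness_max = 230, saturation_min = 0.04) {
  stopifnot(inherits(field, "rgb_field"))
  r <- field$pixels[, , 1]; g <- field$pixels[, , 2]; b <- field$pixels[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  mask <- (mx < brightness_max) | (sat > saturation_min)
  area <- sum(mask) * (field$microns_per_pixel / 1000)^2
  if (!any(mask))
    warning("tissue_mask: no tissue detected; field flagged invalid")
  list(mask = mask, tissue_area_mm2 = area, valid = any(mask))
}

#' Stained area as a fraction of tissue area
#'
#' @param channel per-stain concentration map from [unmix_stains()].
#' @param tissue logical tissue mask.
#' @param od_threshold a pixel is stained when its channel OD exceeds this.
#' @return Fraction in [0, 1].
#' @export
stain_area_fraction <- function(channel, tissue, od_threshold = 0.15) {
  if (!any(tissue)) stop("stain_area_fraction: empty tissue mask")
  sum(channel > od_threshold & tissue) / sum(tissue)
}

# 8-connected component labelling of a logical matrix via the pixel
# adjacency graph. Returns an integer matrix (0 = background).
label_components_8 <- function(mask) {
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0L) return(lab)
  nr <- nrow(mask)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  pos <- matrix(0L, nrow(mask), ncol(mask))
  pos[idx] <- seq_along(idx)
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rr + off[1]; c2 <- cc + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 <= ncol(mask) & c2 >= 1L
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    if (any(ok))
      edges <- c(edges, rbind(pos[idx[ok]], pos[cbind(r2[ok], c2[ok])]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  lab[idx] <- igraph::components(g)$membership
  lab
}

#' Count positive cells in a stain channel
#'
#' Thresholds the channel, applies a morphological opening to remove
#' speckle, labels 8-connected components and keeps those whose physical
#' area falls in `size_range_um2`.
#'
#' @param channel per-stain concentration map.
#' @param tissue logical tissue mask (counting restricted to tissue).
#' @param microns_per_pixel physical pixel size, um.
#' @param od_threshold positivity threshold on the channel OD.
#' @param size_range_um2 `(min, max)` retained component area, um^2.
#' @param opening_radius_px radius of the opening structuring element.
#' @return List: `count`, `cells_per_mm2`, `component_areas_um2`.
#' @export
count_positive_cells <- function(channel, tissue, microns_per_pixel,
                                 od_threshold = 0.15,
                                 size_range_um2 = c(20, 500),
                                 opening_radius_px = 1) {
  if (!any(tissue)) stop("count_positive_cells: empty tissue mask")
  binary <- (channel > od_threshold) & tissue
  if (opening_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * opening_radius_px + 1L, shape = "disc")
    binary <- EBImage::opening(binary * 1, brush) > 0.5
  }
  tissue_area_mm2 <- sum(tissue) * (microns_per_pixel / 1000)^2
  lab <- label_components_8(binary)
  if (max(lab) == 0L) {
    return(list(count = 0L, cells_per_mm2 = 0,
                component_areas_um2 = numeric(0)))
  }
  areas <- tabulate(lab[lab > 0L]) * microns_per_pixel^2
  kept <- areas >= size_range_um2[1] & areas <= size_range_um2[2]
  list(count = sum(kept), cells_per_mm2 = sum(kept) / tissue_area_mm2,
       component_areas_um2 = areas)
}

#' Quantify one histology field
#'
#' End-to-end per-field quantification: OD transform, stain unmixing,
#' tissue masking, then stained-area fraction and (for count stains)
#' positive-cell density on the requested stain channel.
#'
#' @param field an [rgb_field()].
#' @param vectors a [stain_vectors()] matrix.
#' @param stain_channel name or index of the channel of interest.
#' @param mode `"area"` (fraction of tissue) and/or `"count"` (cells).
#' @param od_threshold,size_range_um2,opening_radius_px see
#'   [stain_area_fraction()] and [count_positive_cells()].
#' @param background per-channel background intensity.
#' @return One-row data.frame (`field_id`, `sheep_id`, `lung_label`,
#'   `stain_name`, `valid`, `tissue_area_mm2`, `stain_area_fraction`,
#'   `positive_cell_count`, `cells_per_mm2`).
#' @export
quantify_field <- function(field, vectors, stain_channel = 1,
                           mode = c("area", "count"),
                           od_threshold = 0.15, size_range_um2 = c(20, 500),
                           opening_radius_px = 1,
                           background = c(255, 255, 255)) {
  mode <- match.arg(mode, several.ok = TRUE)
  tis <- tissue_mask(field)
  out <- data.frame(field_id = field$field_id, sheep_id = field$sheep_id,
                    lung_label = field$lung_label,
                    stain_name = field$stain_name, valid = tis$valid,
                    tissue_area_mm2 = tis$tissue_area_mm2,
                    stain_area_fraction = NA_real_,
                    positive_cell_count = NA_integer_,
                    cells_per_mm2 = NA_real_)
  if (!tis$valid) return(out)
  od <- rgb_to_od(field, background)
  chan <- unmix_stains(od, vectors)[[stain_channel]]
  if ("area" %in% mode)
    out$stain_area_fraction <- stain_area_fraction(chan, tis$mask, od_threshold)
  if ("count" %in% mode) {
    cells <- count_positive_cells(chan, tis$mask, field$microns_per_pixel,
                                  od_threshold, size_range_um2,
                                  opening_radius_px)
    out$positive_cell_count <- cells$count
    out$cells_per_mm2 <- cells$cells_per_mm2
  }
  out
}

#' Aggregate per-field quantifications to subject level
#'
#' Unweighted mean over all valid fields within each (sheep, lung, stain)
#' group, matching per-field averaging over every available parenchymal
#' field. Groups with no valid field get `NA` with a warning.
#'
#' @param quants data.frame of per-field rows as from [quantify_field()].
#' @param keys grouping columns.
#' @return data.frame with one row per group: `n_fields` plus the mean of
#'   each numeric quantity.
#' @export
aggregate_fields <- function(quants,
                             keys = c("sheep_id", "lung_label", "stain_name")) {
  stopifnot(all(keys %in% names(quants)))
  groups <- unique(quants[keys])
  vars <- intersect(c("stain_area_fraction", "positive_cell_count",
                      "cells_per_mm2", "tissue_area_mm2"), names(quants))
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- rep(TRUE, nrow(quants))
    for (k in keys) sel <- sel & quants[[k]] == groups[[k]][i]
    sub <- quants[sel & quants$valid, , drop = FALSE]
    res <- groups[i, , drop = FALSE]
    res$n_fields <- nrow(sub)
    for (v in vars)
      res[[v]] <- if (nrow(sub)) mean(sub[[v]]) else NA_real_
    if (nrow(sub) == 0L)
      warning("aggregate_fields: no valid fields for group ",
              paste(unlist(groups[i, ]), collapse = "/"))
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
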