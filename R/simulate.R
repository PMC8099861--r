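#' Configuration for the synthetic CT study generator
#'
#' Defines a phantom longitudinal CT study: two elliptical lung fields
#' (left = Rx, right = CON) filled with spatially correlated Gaussian noise
#' around a parenchymal baseline, with additive radiation effects on the Rx
#' lung. The acute effect raises the Rx mean and spread (denser, more
#' heterogeneous parenchyma, as in pneumonitis); the chronic effect lowers
#' the mean and increases the spatial correlation scale (coarser, more
#' homogeneous texture). Default effect magnitudes carry the sign and
#' approximate size of the paired-lung differences computable from the
#' bundled first-order fixture table.
#'
#' @param image_size `(rows, cols)` in pixels.
#' @param pixel_spacing_mm `(row_mm, col_mm)`.
#' @param baseline_mean_hu,baseline_sd_hu parenchymal HU mean and SD.
#' @param texture_correlation_px Gaussian smoothing scale (px) of the noise
#'   field; 0 = white noise.
#' @param acute_dmean_hu,acute_dsd_hu additive Rx effects at the acute
#'   timepoint.
#' @param chronic_dmean_hu additive Rx mean effect at the chronic timepoint.
#' @param chronic_extra_smooth_px extra Rx smoothing scale at the chronic
#'   timepoint.
#' @param n_sheep number of subjects.
#' @param timepoints study days; the second is treated as acute, the third
#'   (and any later) as chronic.
#' @param lung_semiaxes_px ellipse semi-axes `(row, col)` of each lung.
#' @param background_hu HU value outside the lungs.
#' @return A `ct_sim_config` list.
#' @export
ct_sim_config <- function(image_size = c(96, 96),
                          pixel_spacing_mm = c(1, 1),
                          baseline_mean_hu = -600, baseline_sd_hu = 110,
                          texture_correlation_px = 2,
                          acute_dmean_hu = 140, acute_dsd_hu = 60,
                          chronic_dmean_hu = -110,
                          chronic_extra_smooth_px = 2,
                          n_sheep = 4, timepoints = c(-21, 21, 171),
                          lung_semiaxes_px = c(30, 16),
                          background_hu = -1000) {
  stopifnot(baseline_sd_hu > 0, n_sheep >= 1, length(timepoints) >= 2,
            all(image_size >= 16), texture_correlation_px >= 0)
  structure(as.list(environment()), class = "ct_sim_config")
}

ellipse_mask <- function(size, center, semiaxes) {
  r <- matrix(seq_len(size[1]), size[1], size[2])
  c <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  ((r - center[1]) / semiaxes[1])^2 + ((c - center[2]) / semiaxes[2])^2 <= 1
}

# Smoothed, globally standardized Gaussian random field.
correlated_noise <- function(size, sigma_px) {
  z <- matrix(stats::rnorm(prod(size)), size[1], size[2])
  if (sigma_px > 0)
    z <- as.matrix(EBImage::gblur(z, sigma = sigma_px))
  (z - mean(z)) / stats::sd(z)
}

#' Simulate a longitudinal two-lung CT study
#'
#' Generates one slice per sheep and timepoint. Each lung's parenchyma is
#' an independent correlated Gaussian field rescaled to its target mean/SD,
#' clipped to [-1024, 100] HU; the Rx lung receives the configured acute
#' and chronic effects. Fully reproducible from `seed`.
#'
#' @param config a [ct_sim_config()].
#' @param seed integer RNG seed.
#' @return List with `slices` (list of [ct_slice()]), `masks` (list with
#'   `Rx` and `CON` [lung_mask()], shared by all slices) and `truth`
#'   (data.frame of injected per-lung means/SDs/smoothing scales).
#' @export
simulate_ct_study <- function(config = ct_sim_config(), seed = 1) {
  stopifnot(inherits(config, "ct_sim_config"))
  set.seed(seed)
  size <- config$image_size
  cx <- size[2] / 2
  masks <- list(
    Rx = lung_mask(ellipse_mask(size, c(size[1] / 2, cx / 2),
                                config$lung_semiaxes_px), "Rx"),
    CON = lung_mask(ellipse_mask(size, c(size[1] / 2, cx + cx / 2),
                                 config$lung_semiaxes_px), "CON"))
  phase <- function(i) {
    if (i == 1L) "baseline" else if (i == 2L) "acute" else "chronic"
  }
  slices <- list()
  truth <- NULL
  for (s in seq_len(config$n_sheep)) {
    for (i in seq_along(config$timepoints)) {
      tp <- config$timepoints[i]
      ph <- phase(i)
      img <- matrix(config$background_hu, size[1], size[2])
      for (lung in c("Rx", "CON")) {
        mu <- config$baseline_mean_hu
        sdv <- config$baseline_sd_hu
        sig <- config$texture_correlation_px
        if (lung == "Rx" && ph == "acute") {
          mu <- mu + config$acute_dmean_hu
          sdv <- sdv + config$acute_dsd_hu
        }
        if (lung == "Rx" && ph == "chronic") {
          mu <- mu + config$chronic_dmean_hu
          sig <- sig + config$chronic_extra_smooth_px
        }
        if (mu < -1024 || mu > -242)
          warning("simulate_ct_study: target mean ", mu,
                  " HU lies outside the parenchymal window")
        field <- mu + sdv * correlated_noise(size, sig)
        m <- masks[[lung]]$mask
        img[m] <- field[m]
        truth <- rbind(truth, data.frame(
          sheep_id = sprintf("S%02d", s), timepoint_days = tp, phase = ph,
          lung_label = lung, true_mean_hu = mu, true_sd_hu = sdv,
          smoothing_px = sig))
      }
      img <- pmin(pmax(img, -1024), 100)
      id <- sprintf("S%02d_d%d", s, tp)
      slices[[id]] <- ct_slice(img, config$pixel_spacing_mm,
                               sheep_id = sprintf("S%02d", s),
                               timepoint_days = tp, slice_id = id)
    }
  }
  list(slices = slices, masks = masks, truth = truth)
}

#' Configuration for the synthetic histology field generator
#'
#' A phantom brightfield field composed with Beer-Lambert optics: a diffuse
#' stain region occupying an exact target fraction of the field (stain 1),
#' disjoint discoid "cells" (stain 2), and a uniform counterstain wash
#' (stain 3) that makes every pixel register as tissue.
#'
#' @param field_size `(rows, cols)` px.
#' @param microns_per_pixel physical pixel size, um.
#' @param vectors a [stain_vectors()] 3 x 3 matrix (rows: diffuse stain,
#'   cell stain, counterstain).
#' @param target_fraction target stained-area fraction of the field.
#' @param n_cells number of cells to place.
#' @param cell_area_um2 nominal cell area, um^2.
#' @param diffuse_conc,cell_conc,counterstain_conc stain amplitudes
#'   (dimensionless OD scale).
#' @param blob_scale_px smoothing scale of the diffuse-region shape.
#' @param background_rgb per-channel background intensity.
#' @param noise_sd additive 8-bit Gaussian noise SD.
#' @return A `histo_sim_config` list.
#' @export
histo_sim_config <- function(field_size = c(256, 256),
                             microns_per_pixel = 0.5,
                             vectors = default_histo_vectors(),
                             target_fraction = 0.12, n_cells = 12,
                             cell_area_um2 = 50,
                             diffuse_conc = 0.8, cell_conc = 1.0,
                             counterstain_conc = 0.25,
                             blob_scale_px = 4,
                             background_rgb = c(255, 255, 255),
                             noise_sd = 2) {
  stopifnot(target_fraction >= 0, target_fraction < 1, n_cells >= 0,
            microns_per_pixel > 0, inherits(vectors, "stain_vectors"))
  structure(as.list(environment()), class = "histo_sim_config")
}

#' @rdname histo_sim_config
#' @export
default_histo_vectors <- function() {
  stain_vectors(list(picrosirius = c(0.148, 0.772, 0.618),
                     dab = c(0.268, 0.570, 0.776),
                     haematoxylin = c(0.650, 0.704, 0.286)))
}

disc_offsets <- function(radius_px) {
  r <- ceiling(radius_px)
  dr <- rep(-r:r, times = 2 * r + 1)
  dc <- rep(-r:r, each = 2 * r + 1)
  keep <- dr^2 + dc^2 <= radius_px^2
  cbind(dr[keep], dc[keep])
}

#' Simulate a stained histology field with known ground truth
#'
#' @param config a [histo_sim_config()].
#' @param seed integer RNG seed.
#' @return List: `field` (an [rgb_field()]), `truth` (list with the exact
#'   `stain_area_fraction`, `n_cells`, `cell_area_um2` actually rasterised,
#'   `cell_centers`, and the per-stain concentration maps).
#' @export
simulate_histology_field <- function(config = histo_sim_config(), seed = 1) {
  stopifnot(inherits(config, "histo_sim_config"))
  set.seed(seed)
  size <- config$field_size
  npx <- prod(size)
  conc1 <- matrix(0, size[1], size[2])
  n_sel <- round(config$target_fraction * npx)
  if (n_sel > 0) {
    g <- correlated_noise(size, config$blob_scale_px)
    conc1[order(g, decreasing = TRUE)[seq_len(n_sel)]] <- config$diffuse_conc
  }
  conc2 <- matrix(0, size[1], size[2])
  radius_px <- sqrt(config$cell_area_um2 / pi) / config$microns_per_pixel
  off <- disc_offsets(radius_px)
  margin <- ceiling(radius_px) + 2
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centers) < config$n_cells) {
    if (tries > 1000L * max(config$n_cells, 1L))
      stop("simulate_histology_field: cannot place ", config$n_cells,
           " disjoint cells in the field (infeasible packing)")
    tries <- tries + 1L
    ctr <- c(sample(margin:(size[1] - margin), 1),
             sample(margin:(size[2] - margin), 1))
    if (nrow(centers) > 0 &&
        any((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2 <
            (2 * radius_px + 3)^2)) next
    centers <- rbind(centers, ctr)
    conc2[cbind(ctr[1] + off[, 1], ctr[2] + off[, 2])] <- config$cell_conc
  }
  conc3 <- matrix(config$counterstain_conc, size[1], size[2])
  C <- cbind(as.vector(conc1), as.vector(conc2), as.vector(conc3))
  od <- C %*% unclass(config$vectors)
  pix <- array(0, c(size[1], size[2], 3))
  for (ch in 1:3) {
    I <- config$background_rgb[ch] * 10^(-od[, ch])
    if (config$noise_sd > 0) I <- I + stats::rnorm(npx, 0, config$noise_sd)
    pix[, , ch] <- matrix(round(pmin(pmax(I, 0), 255)), size[1], size[2])
  }
  field <- rgb_field(pix, config$microns_per_pixel,
                     field_id = paste0("sim_seed", seed),
                     stain_name = "PicrosiriusRed")
  truth <- list(
    stain_area_fraction = n_sel / npx,
    n_cells = config$n_cells,
    cell_area_um2 = nrow(off) * config$microns_per_pixel^2,
    cell_centers = centers,
    concentration = list(diffuse = conc1, cells = conc2,
                         counterstain = conc3))
  list(field = field, truth = truth)
}
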