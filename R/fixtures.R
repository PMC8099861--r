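# Study fixtures: the published per-animal radiotherapy plan summary and the
# per-animal CT first-order / texture statistics, transcribed verbatim, plus
# the bronchial-brushing cytokine qPCR summary. These are the worked-example
# inputs for the dose-summary and differencing operations.

#' Radiotherapy plan dose/volume summary (one row per sheep)
#'
#' Planned dose parameters for the clinical target volume (CTV), planning
#' target volume (PTV), left lung (LL, radio-exposed), right lung (RL,
#' control) and right mainstem bronchus (RMB) of the four study sheep.
#' Prescription: 5 fractions of 6 Gy to the PTV isocentre (30 Gy total).
#'
#' @return data.frame, one row per sheep; volumes in cm^3, doses in Gy,
#'   `rl_v1_pct` = % of right-lung volume receiving >= 1 Gy.
#' @export
table1 <- function() {
  df <- data.frame(
    sheep_id = c("ED980", "ED982", "ED983", "ED984"),
    duration_days = c(14, 14, 14, 14),
    ctv_cm3 = c(81.5, 114.3, 83.3, 88.1),
    ctv_min_gy = c(25.98, 26.24, 26.41, 26.72),
    ctv_mean_gy = c(29.89, 29.95, 29.93, 29.74),
    ctv_max_gy = c(32.64, 31.68, 31.47, 31.57),
    ptv_cm3 = c(134.9, 174.5, 133.4, 145.7),
    ptv_min_gy = c(25.25, 25.41, 25.37, 25.21),
    ptv_mean_gy = c(29.76, 29.85, 29.81, 29.46),
    ptv_max_gy = c(32.99, 31.82, 31.74, 31.79),
    ll_vol_cm3 = c(545.0, 666.7, 502.4, 709.7),
    ll_min_gy = c(0.25, 0.24, 0.22, 0.10),
    ll_mean_gy = c(20.34, 19.60, 20.46, 17.48),
    ll_max_gy = c(33.85, 32.67, 32.34, 32.50),
    rl_vol_cm3 = c(665.3, 941.5, 629.8, 888.3),
    rl_min_gy = c(0.14, 0.11, 0.13, 0.09),
    rl_mean_gy = c(0.48, 0.62, 0.54, 0.52),
    rl_max_gy = c(1.61, 11.1, 4.32, 8.87),
    rl_v1_pct = c(3.0, 11.7, 7.9, 7.0),
    rmb_min_gy = c(0.4, 0.6, 0.5, 0.4),
    rmb_mean_gy = c(0.7, 0.9, 0.7, 0.7),
    rmb_max_gy = c(1.0, 1.3, 0.9, 1.0),
    n_fractions = 5L,
    dose_per_fraction_gy = 6)
  class(df) <- c("plan_records", class(df))
  df
}

# Long-format builder for the per-sheep CT statistic tables.
ct_stat_long <- function(values, vars) {
  sheep <- c("ED980", "ED982", "ED983", "ED984")
  tp_final <- c(ED980 = 227L, ED982 = 227L, ED983 = 171L, ED984 = 171L)
  out <- NULL
  k <- 1L
  for (sh in sheep) for (lung in c("CON", "Rx")) {
    tps <- c(-21L, 21L, tp_final[[sh]])
    for (tp in tps) {
      out <- rbind(out, data.frame(
        sheep_id = sh, lung_label = lung, timepoint_days = tp,
        variable_name = vars, value = values[k:(k + length(vars) - 1L)]))
      k <- k + length(vars)
    }
  }
  study_table(out)
}

#' First-order CT statistics of the study lungs (long format)
#'
#' Area, HU mean, HU SD, HU min, HU max, skewness and kurtosis of the lung
#' slice pixel distributions for radio-exposed (Rx) and contralateral
#' control (CON) lungs at baseline (d-21), the acute (d21) and the chronic
#' (d171/d227) timepoint.
#'
#' @return A [study_table()] data.frame.
#' @export
table3 <- function() {
  vars <- c("area_mm2", "hu_mean", "hu_sd", "hu_min", "hu_max", "skewness",
            "kurtosis")
  v <- c(
    # ED980 CON d-21, d21, d227
    1833, -490, 131, -952, 229, 0.68, 1.63,
    1906, -499, 183, -980, 207, 0.59, -0.05,
    2102, -516, 231, -1003, 233, 0.69, -0.25,
    # ED980 Rx
    1843, -503, 133, -815, 51, 0.70, 0.43,
    1955, -378, 229, -850, 164, 0.19, -1.27,
    1858, -605, 158, -919, 420, 2.06, 5.43,
    # ED982 CON
    2739, -693, 79, -1023, -132, 1.57, 6.45,
    1583, -436, 136, -828, 205, 0.66, 0.73,
    1579, -465, 255, -1020, 266, 0.69, -0.51,
    # ED982 Rx
    2450, -642, 104, -1024, 189, 1.36, 4.95,
    1496, -239, 164, -871, 174, -0.49, -0.38,
    1775, -579, 128, -894, 642, 1.51, 6.41,
    # ED983 CON d-21, d21, d171
    1765, -564, 109, -935, 27, 0.52, 0.84,
    1946, -652, 88, -932, 18, 0.54, 1.90,
    1492, -475, 114, -849, 28, 0.31, 0.31,
    # ED983 Rx
    1752, -588, 106, -916, 105, 0.85, 2.48,
    1873, -529, 144, -961, 88, 0.28, -0.04,
    1441, -634, 132, -956, 225, 1.26, 3.96,
    # ED984 CON
    1747, -713, 96, -1004, -198, 0.56, 1.47,
    1607, -659, 98, -945, -50, 0.69, 1.98,
    1442, -574, 198, -988, 558, 1.55, 3.00,
    # ED984 Rx
    1817, -681, 123, -1007, -25, 0.69, 0.67,
    1872, -531, 155, -909, 165, 0.57, 0.25,
    1698, -687, 109, -1018, -50, 0.50, 0.85)
  ct_stat_long(v, vars)
}

#' GLCM texture statistics of the study lungs (long format)
#'
#' Direction-averaged homogeneity, contrast, energy and correlation of the
#' 64-level symmetric GLCMs, plus histogram entropy (bits), for the same
#' lungs and timepoints as [table3()].
#'
#' @return A [study_table()] data.frame.
#' @export
table4 <- function() {
  vars <- c("homogeneity", "contrast", "energy", "correlation", "entropy")
  v <- c(
    # ED980 CON
    0.219, 102.7, 0.0012, 0.50, 6.30,
    0.236, 83.0, 0.0011, 0.68, 6.44,
    0.217, 109.0, 0.0010, 0.62, 6.40,
    # ED980 Rx
    0.216, 108.0, 0.0012, 0.47, 6.29,
    0.222, 101.6, 0.0010, 0.60, 6.40,
    0.261, 74.1, 0.0020, 0.58, 6.00,
    # ED982 CON
    0.256, 88.0, 0.0030, 0.25, 5.88,
    0.256, 68.9, 0.0016, 0.66, 6.04,
    0.224, 105.8, 0.0013, 0.56, 6.32,
    # ED982 Rx
    0.251, 94.1, 0.0021, 0.43, 6.20,
    0.247, 93.4, 0.0017, 0.69, 5.95,
    0.239, 82.8, 0.0017, 0.50, 6.04,
    # ED983 CON
    0.250, 83.3, 0.0017, 0.57, 5.96,
    0.236, 82.7, 0.0018, 0.45, 6.11,
    0.243, 73.0, 0.0015, 0.58, 5.90,
    # ED983 Rx
    0.258, 77.0, 0.0018, 0.60, 5.95,
    0.232, 89.2, 0.0010, 0.63, 6.52,
    0.253, 80.6, 0.0015, 0.65, 6.11,
    # ED984 CON
    0.246, 82.1, 0.0020, 0.47, 5.92,
    0.227, 98.4, 0.0019, 0.36, 5.84,
    0.242, 85.0, 0.0017, 0.58, 6.00,
    # ED984 Rx
    0.245, 82.5, 0.0016, 0.57, 6.10,
    0.220, 101.9, 0.0011, 0.56, 6.18,
    0.254, 79.0, 0.0018, 0.58, 5.92)
  ct_stat_long(v, vars)
}

#' Bronchial-brushing cytokine expression summary
#'
#' Mean and SD of TGF-beta, IL-8 and IL-1-beta expression ratios relative
#' to the ATPase housekeeping gene, per sampling occasion.
#'
#' @return data.frame with `timepoint`, `gene`, `mean_ratio`, `sd_ratio`.
#' @export
table5 <- function() {
  data.frame(
    timepoint = rep(c("baseline", "d11", "d23"), each = 3),
    gene = rep(c("TGFbeta", "IL8", "IL1beta"), 3),
    mean_ratio = c(0.45, 0.60, 0.34,
                   0.40, 0.25, 0.14,
                   0.32, 1.26, 0.40),
    sd_ratio = c(0.66, 0.95, 0.61,
                 0.49, 0.32, 0.20,
                 0.32, 2.54, 0.80))
}
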