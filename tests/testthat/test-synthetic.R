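# Synthetic phantom generators: determinism, truth validity, null behaviour.

test_that("CT study generation is a pure function of config and seed", {
  cfg <- ct_sim_config(image_size = c(48, 48), lung_semiaxes_px = c(14, 8),
                       n_sheep = 1)
  a <- simulate_ct_study(cfg, seed = 5)
  b <- simulate_ct_study(cfg, seed = 5)
  expect_identical(a$slices[[1]]$pixels, b$slices[[1]]$pixels)
  expect_identical(a$truth, b$truth)
  c <- simulate_ct_study(cfg, seed = 6)
  expect_false(identical(a$slices[[1]]$pixels, c$slices[[1]]$pixels))
  # generated HU respect the clipping window and slice invariants
  for (sl in a$slices)
    expect_true(all(sl$pixels >= -1024 & sl$pixels <= 100))
  expect_true(all(a$truth$true_sd_hu > 0))
})

test_that("null CT study shows no systematic paired-lung difference", {
  # white noise (no smoothing) so the pixel SE formula applies
  cfg <- ct_sim_config(texture_correlation_px = 0, acute_dmean_hu = 0,
                       acute_dsd_hu = 0, chronic_dmean_hu = 0,
                       chronic_extra_smooth_px = 0, n_sheep = 2)
  st <- simulate_ct_study(cfg, seed = 42)
  n <- sum(st$masks$Rx$mask)
  expect_gt(n, 1000)
  tab <- hu_mean_table(st)
  d <- rx_con_difference(tab)
  se <- cfg$baseline_sd_hu / sqrt(n)
  expect_true(all(abs(d$diff_value) < 3 * se * sqrt(2)))
})

test_that("default effects reproduce the acute-up / chronic-down HU pattern", {
  st <- simulate_ct_study(seed = 7)
  d <- rx_con_difference(hu_mean_table(st))
  ph <- study_phase(d$timepoint_days)
  expect_true(all(d$diff_value[ph == "acute"] > 0))
  expect_true(all(d$diff_value[ph == "chronic"] < 0))
  # truth table records the injected effects
  tr <- st$truth
  expect_equal(unique(tr$true_mean_hu[tr$phase == "acute" &
                                        tr$lung_label == "Rx"]), -460)
  expect_equal(unique(tr$true_mean_hu[tr$phase == "chronic" &
                                        tr$lung_label == "Rx"]), -710)
})

test_that("extra smoothing in the chronic Rx lung raises GLCM homogeneity", {
  ok <- 0
  for (s in 1:10) {
    st <- simulate_ct_study(seed = 200 + s)
    sl_base <- st$slices[[1]]   # baseline
    sl_chr <- st$slices[[3]]    # chronic
    t_base <- ct_texture(sl_base, st$masks$Rx)
    t_chr <- ct_texture(sl_chr, st$masks$Rx)
    if (t_chr$homogeneity > t_base$homogeneity) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("histology generation is deterministic with valid truth", {
  cfg <- histo_sim_config(field_size = c(128, 128), n_cells = 5)
  a <- simulate_histology_field(cfg, seed = 3)
  b <- simulate_histology_field(cfg, seed = 3)
  expect_identical(a$field$pixels, b$field$pixels)
  expect_equal(a$truth$stain_area_fraction, round(0.12 * 128^2) / 128^2)
  expect_equal(nrow(a$truth$cell_centers), 5)
  expect_true(a$truth$cell_area_um2 >= 20 && a$truth$cell_area_um2 <= 500)
  # empty field: blank background, zero quantification
  cfg0 <- histo_sim_config(field_size = c(64, 64), target_fraction = 0,
                           n_cells = 0, counterstain_conc = 0.25)
  sim0 <- simulate_histology_field(cfg0, seed = 1)
  q <- quantify_field(sim0$field, cfg0$vectors, 1, c("area", "count"))
  expect_equal(q$stain_area_fraction, 0)
  expect_equal(q$positive_cell_count, 0L)
  # infeasible packing errors out
  expect_error(
    simulate_histology_field(
      histo_sim_config(field_size = c(40, 40), n_cells = 500), seed = 1),
    "packing")
})

test_that("noiseless composition unmixes to the generated concentration maps", {
  cfg <- histo_sim_config(field_size = c(96, 96), noise_sd = 0, n_cells = 4)
  sim <- simulate_histology_field(cfg, seed = 2)
  ch <- unmix_stains(rgb_to_od(sim$field), cfg$vectors)
  err1 <- abs(ch[[1]] - sim$truth$concentration$diffuse)
  err2 <- abs(ch[[2]] - sim$truth$concentration$cells)
  # 8-bit quantization limits accuracy; the bulk of pixels recover closely
  expect_lt(mean(err1), 0.02)
  expect_lt(mean(err2), 0.02)
  expect_lt(stats::quantile(err1, 0.99), 0.05)
  expect_lt(stats::quantile(err2, 0.99), 0.05)
})

test_that("qPCR simulation matches its closed form and is seed-stable", {
  a <- simulate_qpcr(2, 10^(0:-3), noise_sd = 0.1, seed = 4)
  b <- simulate_qpcr(2, 10^(0:-3), noise_sd = 0.1, seed = 4)
  expect_identical(a, b)
  noiseless <- simulate_qpcr(2, 10^(0:-3), noise_sd = 0)
  expect_equal(fit_standard_curve(noiseless$log10_dilution, noiseless$cq)$slope,
               -1 / log10(2), tolerance = 1e-9)
})
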