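# Colour deconvolution, tissue masking, stain quantification and counting.

white_field <- function(n = 16, mpp = 1) {
  rgb_field(array(255, c(n, n, 3)), mpp)
}

test_that("optical density follows Beer-Lambert with the +1 offset", {
  f <- white_field()
  expect_equal(rgb_to_od(f), array(0, c(16, 16, 3)))

  # I + 1 = background / 10  =>  OD = 1
  pix <- array(24.5, c(4, 4, 3))
  od <- rgb_to_od(rgb_field(pix, 1))
  expect_equal(od, array(1, c(4, 4, 3)), tolerance = 1e-12)

  # per-pixel scalar oracle
  set.seed(1)
  pix <- array(runif(4 * 4 * 3, 0, 255), c(4, 4, 3))
  od <- rgb_to_od(rgb_field(pix, 1))
  for (i in 1:4) for (j in 1:4) for (c in 1:3) {
    expect_equal(od[i, j, c],
                 max(-log10((pix[i, j, c] + 1) / 255), 0),
                 tolerance = 1e-12)
  }
})

test_that("unmixing is the matrix identity on pure stains", {
  v <- default_histo_vectors()
  # pure stain 1 at OD amplitude a
  a <- 0.7
  od <- array(0, c(5, 5, 3))
  for (c in 1:3) od[, , c] <- a * v[1, c]
  ch <- unmix_stains(od, v)
  expect_equal(ch[[1]], matrix(a, 5, 5), tolerance = 1e-10)
  expect_equal(ch[[2]], matrix(0, 5, 5), tolerance = 1e-10)
  expect_equal(ch[[3]], matrix(0, 5, 5), tolerance = 1e-10)

  # zero OD image
  ch0 <- unmix_stains(array(0, c(3, 3, 3)), v)
  expect_true(all(vapply(ch0, max, 1) == 0))

  # compose-then-unmix round trip before quantization
  set.seed(2)
  conc <- lapply(1:3, function(k) matrix(runif(36, 0, 1.5), 6, 6))
  od <- array(0, c(6, 6, 3))
  for (c in 1:3)
    od[, , c] <- conc[[1]] * v[1, c] + conc[[2]] * v[2, c] + conc[[3]] * v[3, c]
  rec <- unmix_stains(od, v)
  for (k in 1:3) expect_equal(rec[[k]], conc[[k]], tolerance = 1e-6)
})

test_that("stain vector construction validates and completes to 3 rows", {
  v2 <- stain_vectors(list(a = c(1, 0, 0), b = c(0, 1, 0)))
  expect_equal(nrow(v2), 3L)
  expect_equal(unname(rowSums(unclass(v2)^2)), rep(1, 3), tolerance = 1e-12)
  expect_error(stain_vectors(list(a = c(1, 0, 0), b = c(2, 0, 0))),
               "collinear")
  # calibration recovers a known vector from a pure-stain image
  v <- stain_vectors_hdab()
  pix <- array(0, c(8, 8, 3))
  for (c in 1:3) pix[, , c] <- 255 * 10^(-0.8 * v[2, c]) - 1
  est <- calibrate_stain_vector(rgb_field(pix, 1))
  expect_equal(est, unname(v[2, ]), tolerance = 1e-3)
})

test_that("tissue mask separates background white from stained tissue", {
  expect_warning(t0 <- tissue_mask(white_field()), "invalid")
  expect_false(t0$valid)

  # half white, half pink
  pix <- array(255, c(10, 10, 3))
  pix[1:5, , 1] <- 230; pix[1:5, , 2] <- 160; pix[1:5, , 3] <- 180
  tm <- tissue_mask(rgb_field(pix, 2))
  expect_equal(mean(tm$mask), 0.5)
  expect_equal(tm$tissue_area_mm2, 50 * (2 / 1000)^2)

  # fully stained field
  pix2 <- array(120, c(6, 6, 3)); pix2[, , 1] <- 180
  expect_true(all(tissue_mask(rgb_field(pix2, 1))$mask))
})

test_that("stain area fraction is exact on crisp channels and monotone in threshold", {
  ch <- matrix(0, 10, 10); ch[1:3, ] <- 0.8
  tis <- matrix(TRUE, 10, 10)
  expect_equal(stain_area_fraction(ch, tis), 0.3)
  expect_equal(stain_area_fraction(matrix(0, 5, 5), matrix(TRUE, 5, 5)), 0)
  expect_equal(stain_area_fraction(ch, tis, od_threshold = 1), 0)
  set.seed(3)
  ch2 <- matrix(runif(400), 20, 20)
  fr <- vapply(seq(0, 1, 0.1),
               function(th) stain_area_fraction(ch2, matrix(TRUE, 20, 20), th),
               1)
  expect_true(all(diff(fr) <= 0))
})

test_that("cell counting is exact, size-filtered, and invariant to rigid motion", {
  tis <- matrix(TRUE, 60, 60)
  ch <- matrix(0, 60, 60)
  centers <- rbind(c(10, 10), c(10, 40), c(40, 15), c(45, 45))
  for (i in seq_len(nrow(centers))) {
    for (dr in -3:3) for (dc in -3:3) {
      if (dr^2 + dc^2 <= 9)
        ch[centers[i, 1] + dr, centers[i, 2] + dc] <- 0.9
    }
  }
  res <- count_positive_cells(ch, tis, microns_per_pixel = 1,
                              size_range_um2 = c(5, 100))
  expect_equal(res$count, 4)
  expect_equal(res$cells_per_mm2, 4 / (3600 * 1e-6))

  # blank channel
  expect_equal(count_positive_cells(matrix(0, 10, 10), matrix(TRUE, 10, 10),
                                    1)$count, 0)

  # giant component rejected by the size filter
  big <- matrix(0.9, 60, 60)
  expect_equal(count_positive_cells(big, tis, 1,
                                    size_range_um2 = c(5, 100))$count, 0)

  # translation and 90-degree rotation leave the count unchanged
  sh <- matrix(0, 60, 60); sh[6:60, 6:60] <- ch[1:55, 1:55]
  expect_equal(count_positive_cells(sh, tis, 1,
                                    size_range_um2 = c(5, 100))$count, 4)
  rot <- t(ch)[, 60:1]
  expect_equal(count_positive_cells(rot, tis, 1,
                                    size_range_um2 = c(5, 100))$count, 4)

  # 8-connectivity: two diagonal speckles below min size vanish; a diagonal
  # chain forms one component
  diagm <- matrix(0, 20, 20)
  for (k in 5:12) diagm[k, k] <- 0.9
  res_d <- count_positive_cells(diagm, matrix(TRUE, 20, 20), 3,
                                od_threshold = 0.5,
                                size_range_um2 = c(9, 1000),
                                opening_radius_px = 0)
  expect_equal(res_d$count, 1)
})

test_that("field aggregation averages valid fields per subject and lung", {
  q <- data.frame(
    field_id = 1:5,
    sheep_id = c("A", "A", "A", "B", "B"),
    lung_label = c("Rx", "Rx", "Rx", "CON", "CON"),
    stain_name = "PicrosiriusRed",
    valid = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    tissue_area_mm2 = 1,
    stain_area_fraction = c(0.10, 0.20, 0.99, 0.30, 0.30),
    positive_cell_count = c(1L, 3L, 0L, 2L, 4L),
    cells_per_mm2 = c(1, 3, 0, 2, 4))
  ag <- aggregate_fields(q)
  a <- ag[ag$sheep_id == "A", ]
  expect_equal(a$stain_area_fraction, 0.15)  # invalid field excluded
  expect_equal(a$n_fields, 2)
  b <- ag[ag$sheep_id == "B", ]
  expect_equal(b$stain_area_fraction, 0.30)
  expect_equal(b$cells_per_mm2, 3)
  # order invariance
  ag2 <- aggregate_fields(q[sample(5), ])
  expect_equal(ag2[order(ag2$sheep_id), ]$stain_area_fraction,
               ag[order(ag$sheep_id), ]$stain_area_fraction)
  # no valid fields -> NA with warning
  q$valid <- FALSE
  ws <- capture_warnings(ag3 <- aggregate_fields(q))
  expect_match(ws, "no valid fields", all = TRUE)
  expect_true(all(is.na(ag3$stain_area_fraction)))
})

test_that("mean aggregation equals the arithmetic oracle on many fields", {
  set.seed(9)
  fr <- runif(50, 0, 0.4)
  q <- data.frame(field_id = 1:50, sheep_id = "S", lung_label = "Rx",
                  stain_name = "CD31-DAB", valid = TRUE,
                  tissue_area_mm2 = 1, stain_area_fraction = fr,
                  positive_cell_count = 0L, cells_per_mm2 = 0)
  expect_equal(aggregate_fields(q)$stain_area_fraction, sum(fr) / 50,
               tolerance = 1e-12)
})
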