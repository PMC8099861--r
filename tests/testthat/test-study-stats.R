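# Paired-lung differencing, ANOVA, correlation, normality and qPCR.

test_that("paired-lung differencing is exact and antisymmetric", {
  t3 <- table3()
  d <- rx_con_difference(t3)
  ed980 <- d[d$sheep_id == "ED980" & d$timepoint_days == 21 &
               d$variable_name == "hu_mean", ]
  expect_equal(ed980$diff_value, 121)  # -378 - (-499)

  # identical lungs difference to zero
  same <- t3
  same$value <- ave(same$value,
                    interaction(same$sheep_id, same$timepoint_days,
                                same$variable_name))
  expect_true(all(abs(rx_con_difference(same)$diff_value) < 1e-9))

  # swapping lung labels negates the table
  sw <- t3
  sw$lung_label <- ifelse(t3$lung_label == "Rx", "CON", "Rx")
  dsw <- rx_con_difference(sw)
  expect_equal(dsw$diff_value, -d$diff_value)

  # unpaired rows are dropped with a warning
  expect_warning(d2 <- rx_con_difference(t3[-1, ]), "unpaired")
  expect_equal(nrow(d2), nrow(d) - 1L)
  expect_error(rx_con_difference(t3[t3$lung_label == "Rx", ]), "no paired")
})

test_that("repeated-measures ANOVA matches its sums-of-squares oracle", {
  d3 <- rx_con_difference(table3())
  a <- rm_anova(d3, "hu_sd", transform = "none")
  expect_equal(a$df, c(2, 6))  # 4 sheep x 3 phases

  sub <- d3[d3$variable_name == "hu_sd", ]
  o <- oracle_rm_ss(sub$diff_value, sub$sheep_id,
                    study_phase(sub$timepoint_days))
  expect_equal(a$f_value, o$f, tolerance = 1e-10)
  expect_equal(a$table$ss, c(o$ss_time, o$ss_subject, o$ss_error),
               tolerance = 1e-10)
  expect_equal(sum(a$table$ss), o$ss_total, tolerance = 1e-8)

  # cross-check against the standard linear-model fit
  fit <- stats::aov(diff_value ~ factor(study_phase(timepoint_days)) +
                      factor(sheep_id), data = sub)
  expect_equal(a$f_value, summary(fit)[[1]]$`F value`[1], tolerance = 1e-10)
  expect_equal(a$p_value, summary(fit)[[1]]$`Pr(>F)`[1], tolerance = 1e-10)

  # random balanced designs
  for (s in 1:10) {
    set.seed(s)
    ns <- sample(2:5, 1); nt <- sample(2:4, 1)
    dd <- expand.grid(sheep_id = paste0("S", 1:ns),
                      timepoint_days = c(-21, 21, 171, 300)[1:nt])
    dd$variable_name <- "v"; dd$diff_value <- rnorm(nrow(dd))
    a <- rm_anova(dd, transform = "none", time_factor = "days")
    o <- oracle_rm_ss(dd$diff_value, dd$sheep_id, dd$timepoint_days)
    expect_equal(a$f_value, o$f, tolerance = 1e-10)
    expect_equal(a$df, c(nt - 1, (nt - 1) * (ns - 1)))
  }

  # constant differences: no time effect at all
  dd <- expand.grid(sheep_id = c("a", "b"), timepoint_days = c(1, 2, 3))
  dd$variable_name <- "v"; dd$diff_value <- 5
  ac <- rm_anova(dd, transform = "none", time_factor = "days")
  expect_equal(ac$table$ss[1], 0)
  expect_equal(ac$f_value, 0)

  # unbalanced designs are refused
  expect_error(rm_anova(dd[-1, ], transform = "none", time_factor = "days"),
               "balanced")
})

test_that("one-way ANOVA matches the textbook partition and the t-test identity", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  a <- one_way_anova(g)
  expect_equal(a$f_value, 0)
  expect_equal(a$p_value, 1)

  for (s in 1:10) {
    set.seed(s)
    g <- list(x = rnorm(5), y = rnorm(7, 1), z = rnorm(4, -1))
    a <- one_way_anova(g)
    o <- oracle_oneway(g)
    expect_equal(a$f_value, o$f, tolerance = 1e-10)
    expect_equal(a$p_value, o$p, tolerance = 1e-10)
    expect_equal(a$table$ss, c(o$ss_between, o$ss_within), tolerance = 1e-10)
  }

  # two groups: F equals the squared pooled-variance t statistic
  set.seed(11)
  x <- rnorm(8); y <- rnorm(9, 0.5)
  a2 <- one_way_anova(list(x = x, y = y))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(a2$f_value, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("Pearson correlation matches the closed-form t conversion", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  set.seed(4)
  x <- rnorm(8); y <- rnorm(8)
  pc <- pearson_correlation(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((8 - 2) / (1 - r^2))
  expect_equal(pc$r, r, tolerance = 1e-12)
  expect_equal(pc$p_value, 2 * stats::pt(-abs(tstat), 6), tolerance = 1e-12)
  expect_true(pearson_correlation(x, rep(1, 8))$degenerate)
})

test_that("KS normality test flags estimated parameters and behaves sanely", {
  set.seed(5)
  good <- ks_normality(rnorm(1000))
  expect_true(good$p_value > 0.05)
  expect_true(good$params_estimated)
  expect_true(good$statistic >= 0 && good$statistic <= 1)
  bad <- ks_normality(rlnorm(1000, sdlog = 1.5))
  expect_true(bad$p_value < 0.01)
  expect_true(ks_normality(rep(2, 10))$degenerate)
})

test_that("standard-curve efficiency inverts the slope exactly", {
  # slope -1/log10(2) <=> E = 2
  ld <- 0:-4
  cq <- 20 - ld / log10(2)
  cu <- fit_standard_curve(ld, cq)
  expect_equal(cu$efficiency, 2, tolerance = 1e-9)
  expect_equal(cu$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(cu$r_squared, 1, tolerance = 1e-12)

  sim <- simulate_qpcr(efficiency = 1.95, noise_sd = 0)
  cu2 <- fit_standard_curve(sim$log10_dilution, sim$cq)
  expect_equal(cu2$efficiency, 1.95, tolerance = 1e-6)

  expect_error(fit_standard_curve(0:-3, c(10, 11, 12, 13) * 0 + 5),
               "slope")
})

test_that("relative quantification follows the efficiency model", {
  sim <- simulate_qpcr(efficiency = 2, noise_sd = 0, intercept = 18)
  cu <- fit_standard_curve(sim$log10_dilution, sim$cq)
  # identical Cq, identical curves
  expect_equal(relative_quantification(20, 20, cu, cu), 1, tolerance = 1e-9)
  # one cycle earlier doubles the ratio at E = 2
  expect_equal(relative_quantification(19, 20, cu, cu), 2, tolerance = 1e-6)
  # known true ratio 0.5 recovered through two different curves
  simr <- simulate_qpcr(efficiency = 1.97, noise_sd = 0, intercept = 21)
  cur <- fit_standard_curve(simr$log10_dilution, simr$cq)
  cq_t <- 18 - log10(0.5 * 0.2) / log10(2)
  cq_r <- 21 - log10(0.2) / log10(1.97)
  expect_equal(relative_quantification(cq_t, cq_r, cu, cur), 0.5,
               tolerance = 1e-6)
})

test_that("rm_anova p-values are uniform under the null (small Monte Carlo)", {
  set.seed(77)
  ps <- replicate(200, {
    dd <- expand.grid(sheep_id = paste0("S", 1:4),
                      timepoint_days = c(-21, 21, 171))
    dd$variable_name <- "v"; dd$diff_value <- rnorm(12)
    rm_anova(dd, transform = "none")$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
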