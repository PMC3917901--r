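test_that("direct_unmix inverts the forward model exactly", {
  # worked example: g0 = 7, a0 = 3, ra = 0.6, rg = 0.114
  f525 <- 7 + 3
  f585 <- 0.114 * 7 + 0.6 * 3
  expect_equal(f525, 10)
  expect_equal(f585, 2.598)
  expect_equal(direct_unmix(f525, f585, 0.6, 0.114), 7)

  # property: random tuples invert to machine precision
  set.seed(31)
  n <- 2000
  g <- runif(n, -50, 500); a <- runif(n, 0, 300)
  ra <- runif(n, 0.2, 0.9); rg <- runif(n, 0, 0.15)
  ok <- abs(ra - rg) > 0.05
  est <- direct_unmix((g + a)[ok], (rg * g + ra * a)[ok], ra[ok], rg[ok])
  expect_lt(max(abs(est - g[ok]) / pmax(abs(g[ok]), 1)), 1e-11)
})

test_that("direct_unmix limiting forms and error contract hold", {
  # pure autofluorescence: zero reporter signal
  expect_equal(direct_unmix(100, 50, 0.5, 0.114), 0)
  # rg = 0 reduces to the classic two-channel unmix
  set.seed(5)
  for (rep in 1:20) {
    f525 <- runif(1, 1, 100); f585 <- runif(1, 1, 50); ra <- runif(1, 0.3, 0.9)
    expect_equal(direct_unmix(f525, f585, ra, 0), f525 - f585 / ra)
  }
  expect_error(direct_unmix(10, 5, 0.5, 0.5 - 1e-8),
               class = "platemix_illconditioned_error")
})

test_that("sensitivity of the unmixed signal to ra matches its analytic form", {
  f525 <- 80; f585 <- 25; ra <- 0.55; rg <- 0.114
  h <- 1e-6
  numeric_grad <- (direct_unmix(f525, f585, ra + h, rg) -
                   direct_unmix(f525, f585, ra - h, rg)) / (2 * h)
  analytic <- (f585 - rg * f525) / (ra - rg)^2
  expect_equal(numeric_grad, analytic, tolerance = 1e-6)
})

test_that("fit_ra recovers a constant emission ratio", {
  sc <- synthetic_scenario(ra_profile = list(type = "constant", value = 0.45),
                           expression = list(type = "off", gmax = 0,
                                             t_on = 2, tau = 2),
                           seed = 17)
  sim <- generate_experiment(sc, n_media = 2, n_wildtype = 2, n_tagged = 1,
                             n_timepoints = 80, dt_h = 0.25)
  corr <- apply_media_correction(sim$dataset, fit_media(sim$dataset))
  ra <- fit_ra(corr)
  grid <- seq(ra$od_support[1], ra$od_support[2], length.out = 30)
  pr <- gp_predict(ra$gp, grid)
  expect_true(all(abs(pr$mean + ra$offset - 0.45) <= 2 * pr$sd + 0.01))
  med <- stats::median(corr$od[, wells_by_role(corr, "wildtype")])
  expect_lt(abs(gp_predict(ra$gp, med)$mean + ra$offset - 0.45), 0.02)
})

test_that("fit_ra interpolates a noiseless sigmoidal ratio and stays monotone", {
  sc <- synthetic_scenario(
    noise_sd = list(od = 0, f525 = 0, f585 = 0),
    media_drift = list(od0 = 0, od_slope = 0, f525_0 = 0, f525_slope = 0,
                       f585_0 = 0, f585_slope = 0),
    expression = list(type = "off", gmax = 0, t_on = 2, tau = 2), seed = 3)
  sim <- generate_experiment(sc, n_media = 1, n_wildtype = 2, n_tagged = 1,
                             n_timepoints = 60, dt_h = 0.33)
  # media background is exactly zero: use the dataset as-is
  d <- sim$dataset
  d$meta$media_corrected <- TRUE
  d$layout <- d$layout[d$layout$role != "media", ]
  d$od <- d$od[, d$layout$well]; d$f525 <- d$f525[, d$layout$well]
  d$f585 <- d$f585[, d$layout$well]
  ra <- fit_ra(d)
  wt_od <- as.vector(d$od[, wells_by_role(d, "wildtype")])
  fit_vals <- gp_predict(ra$gp, wt_od)$mean + ra$offset
  # the windowed noise estimate cannot know the data are noiseless (it sees
  # the curve's slope across the window), so interpolation is near- rather
  # than exactly noise-free
  expect_lt(max(abs(fit_vals - sim$truth$ra_profile(wt_od))), 5e-3)
  grid <- seq(ra$od_support[1], ra$od_support[2], length.out = 50)
  expect_true(all(diff(gp_predict(ra$gp, grid)$mean) > -1e-6))
})

test_that("fit_ra tracks a rising sigmoid within posterior uncertainty", {
  run <- default_run()
  ra <- run$ra
  grid <- seq(ra$od_support[1] + 0.05, ra$od_support[2], length.out = 40)
  pr <- gp_predict(ra$gp, grid)
  truth <- run$sim$truth$ra_profile(grid)
  expect_true(mean(abs(pr$mean + ra$offset - truth) <= 2 * pr$sd + 0.015) >= 0.9)
  # fitted curve rises monotonically across the support
  expect_true(all(diff(pr$mean) > -1e-6))
})

test_that("ra_at evaluates, samples, and flags consistently", {
  run <- default_run()
  ra <- run$ra
  od <- seq(0.3, 1.2, length.out = 20)
  r1 <- ra_at(ra, od, 5, seed = 42)
  r2 <- ra_at(ra, od, 5, seed = 42)
  expect_identical(r1$samples, r2$samples)

  big <- ra_at(ra, od, 4000, seed = 1)
  pr_mean <- big$mean
  se <- apply(big$samples, 1, stats::sd) / sqrt(4000)
  expect_true(all(abs(rowMeans(big$samples) - pr_mean) < 4 * se + 1e-8))
  expect_true(all(big$noise_sd > 0))

  out <- ra_at(ra, c(0.01, 0.5, 5), 2, seed = 1)
  expect_identical(out$extrapolated, c(TRUE, FALSE, TRUE))
})

test_that("direct pipeline recovers known expression on a noisy experiment", {
  run <- default_run()
  est <- direct_pipeline(run$corrected, run$cal)[["tagged_1"]]
  truth <- truth_per_cell_cal(run)
  dens <- truth_density_cal(run)
  # channel noise propagated through the unmixing, in per-cell units
  sc <- run$sim$truth$scenario
  ra_true <- run$sim$truth$ra_profile(
    rowMeans(sapply(paste0("T", 1:3), function(w)
      run$sim$truth$wells[[w]]$od_cells)))
  floor_pc <- sqrt(sc$noise_sd$f585^2 + ra_true^2 * sc$noise_sd$f525^2) /
    abs(ra_true - sc$rg_true) / dens
  hi <- truth > 5 * floor_pc
  expect_gt(sum(hi), 50)
  expect_lt(max(abs(est$per_cell_mean[hi] / truth[hi] - 1)), 0.10)
  expect_identical(est$method, "direct")
  expect_true(all(is.na(est$per_cell_sd)))
})

test_that("direct pipeline is near-exact on noiseless data without smoothing", {
  sc <- synthetic_scenario(
    noise_sd = list(od = 0, f525 = 0, f585 = 0),
    media_drift = list(od0 = 0, od_slope = 0, f525_0 = 0, f525_slope = 0,
                       f585_0 = 0, f585_slope = 0),
    growth = list(d0_wildtype = 0.1, d0_tagged = 0.1, rate = 0.35,
                  capacity = 1.2, rate_cv = 0),
    od_map = list(slope = 1, shoulder = 1e6),   # OD == density
    seed = 9)
  sim <- generate_experiment(sc, n_media = 1, n_wildtype = 2, n_tagged = 2,
                             n_timepoints = 60, dt_h = 0.33)
  d <- sim$dataset
  d$meta$media_corrected <- TRUE
  d$layout <- d$layout[d$layout$role != "media", ]
  for (ch in c("od", "f525", "f585")) d[[ch]] <- d[[ch]][, d$layout$well]
  factors <- 2^(0:7)
  cal <- fit_od_calibration(1.2 / factors, factors)
  est <- direct_pipeline(d, cal, smooth = FALSE)[["tagged_1"]]
  truth <- sim$truth$wells[["T1"]]$per_cell * 1.2
  keep <- truth > 1   # skip pre-induction zeros where relative error is undefined
  expect_lt(max(abs(est$per_cell_mean[keep] / truth[keep] - 1)), 0.005)
})

test_that("subtraction baseline vanishes when tagged equals wild-type", {
  times <- seq(0, 8, length.out = 40)
  f <- function(t) 20 + 5 * t
  rows <- do.call(rbind, lapply(c("W1", "T1"), function(w) {
    data.frame(well = w, time_h = times, od = 0.2 + 0.05 * times,
               f525 = f(times), f585 = f(times) / 2)
  }))
  layout <- data.frame(well = c("W1", "T1"), role = c("wildtype", "tagged"),
                       strain = c("wt", "tag"), condition = "x",
                       replicate_group = c("wt", "g"))
  d <- plate_dataset(rows, layout)
  factors <- 2^(0:7)
  cal <- fit_od_calibration(0.6 / factors, factors)
  est <- subtraction_baseline(d, cal)[["g"]]
  expect_lt(max(abs(est$per_cell_mean)), 1e-6)
})

test_that("subtraction baseline goes negative when tagged autofluorescence is lower", {
  sc <- synthetic_scenario(
    autofl_per_cell = list(wildtype = 100, tagged = 80, od_slope = 0),
    expression = list(type = "off", gmax = 0, t_on = 2, tau = 2))
  sim <- generate_experiment(sc, n_media = 2, n_wildtype = 2, n_tagged = 2,
                             n_timepoints = 60, dt_h = 0.33)
  corr <- apply_media_correction(sim$dataset, fit_media(sim$dataset))
  dil <- generate_dilution_series()
  cal <- fit_od_calibration(dil$table$od, dil$table$dilution_factor)
  est <- subtraction_baseline(corr, cal)[["tagged_1"]]
  m <- mean(est$per_cell_mean)
  se <- stats::sd(est$per_cell_mean) / sqrt(length(est$per_cell_mean))
  expect_lt(m, -2 * se)
  expect_gt(mean(est$per_cell_mean < 0), 0.9)
})

test_that("subtraction agrees with direct unmixing when its assumptions hold", {
  # equal autofluorescence per cell, equal growth, real expression
  sc <- synthetic_scenario(
    growth = list(d0_wildtype = 0.12, d0_tagged = 0.12, rate = 0.35,
                  capacity = 1.2, rate_cv = 0),
    seed = 23)
  sim <- generate_experiment(sc, n_media = 2, n_wildtype = 3, n_tagged = 3,
                             n_timepoints = 80, dt_h = 0.25)
  corr <- apply_media_correction(sim$dataset, fit_media(sim$dataset))
  dil <- generate_dilution_series()
  cal <- fit_od_calibration(dil$table$od, dil$table$dilution_factor)
  sub <- subtraction_baseline(corr, cal)[["tagged_1"]]
  dir <- direct_pipeline(corr, cal)[["tagged_1"]]
  truth <- rowMeans(sapply(paste0("T", 1:3), function(w)
    sim$truth$wells[[w]]$per_cell)) * max(dil$truth$density)
  hi <- truth > 100
  # the subtraction estimate keeps rg*g in the 585 channel out of the
  # correction, so agreement is approximate, within a few percent
  expect_lt(stats::median(abs(sub$per_cell_mean[hi] - dir$per_cell_mean[hi]) /
                            truth[hi]), 0.05)
})
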