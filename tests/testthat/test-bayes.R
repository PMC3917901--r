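test_that("the likelihood maximizer coincides with the direct unmixing estimate", {
  set.seed(77)
  n <- 2000
  f525 <- runif(n, 1, 500); f585 <- runif(n, 0, 250)
  ra <- runif(n, 0.2, 0.9); rg <- runif(n, 0, 0.15)
  s525 <- runif(n, 0.5, 10); s585 <- runif(n, 0.5, 10)
  keep <- abs(ra - rg) > 0.05
  p <- g_likelihood_params(f525[keep], f585[keep], ra[keep], rg[keep],
                           s525[keep], s585[keep])
  d <- direct_unmix(f525[keep], f585[keep], ra[keep], rg[keep])
  expect_lt(max(abs(p$mu_g - d) / pmax(abs(d), 1)), 1e-13)
  expect_true(all(p$sd_g > 0))
})

test_that("the likelihood width follows its closed form and noiseless limit", {
  p <- g_likelihood_params(10, 3, 0.5, 0, 2, 2)
  expect_equal(p$sd_g, 2 * sqrt(5))           # sigma * sqrt(1 + ra^2) / ra
  tiny <- g_likelihood_params(10, 3, 0.5, 0, 1e-12, 1e-12)
  expect_lt(tiny$sd_g, 1e-11)
  expect_error(g_likelihood_params(10, 3, 0.5, 0.5, 1, 1),
               class = "platemix_illconditioned_error")
  expect_error(g_likelihood_params(10, 3, 0.5, 0.1, 0, 1),
               class = "platemix_domain_error")
})

test_that("rejection draws match the closed-form Gaussian distribution", {
  pass <- vapply(1:20, function(s) {
    x <- sample_g(80, 30, 0.55, 0.114, 4, 3, 2000, seed = 5000 + s,
                  sampler = "rejection")
    p <- g_likelihood_params(80, 30, 0.55, 0.114, 4, 3)
    suppressWarnings(stats::ks.test(x, "pnorm", p$mu_g, p$sd_g)$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.9)
})

test_that("both samplers are unbiased, deterministic, and seed-isolated", {
  p <- g_likelihood_params(120, 40, 0.6, 0.114, 5, 4)
  for (sampler in c("gaussian", "rejection")) {
    x1 <- sample_g(120, 40, 0.6, 0.114, 5, 4, 5000, seed = 9, sampler = sampler)
    x2 <- sample_g(120, 40, 0.6, 0.114, 5, 4, 5000, seed = 9, sampler = sampler)
    expect_identical(x1, x2)
    expect_lt(abs(mean(x1) - p$mu_g), 3 * p$sd_g / sqrt(5000))
    expect_equal(stats::sd(x1), p$sd_g, tolerance = 0.05)
  }
})

test_that("windowed noise estimation behaves on constant, noisy, and trending series", {
  times <- seq(0, 40, length.out = 200)
  mk <- function(f525) {
    rows <- data.frame(well = "X1", time_h = times, od = 0.1,
                       f525 = f525, f585 = f525 / 2)
    layout <- data.frame(well = "X1", role = "tagged", strain = "s",
                         condition = "c", replicate_group = "g")
    plate_dataset(rows, layout)
  }
  # constant channel: floor everywhere
  nz <- estimate_noise(mk(rep(7, 200)), "X1", 20)
  expect_true(all(nz$sigma525 == 1e-12))

  # i.i.d. Gaussian noise: estimates live in the chi-square band for n = 20
  set.seed(12)
  nz <- estimate_noise(mk(100 + rnorm(200, 0, 5)), "X1", 20)
  band <- 5 * sqrt(stats::qchisq(c(0.005, 0.995), df = 19) / 19)
  expect_gte(mean(nz$sigma525 >= band[1] & nz$sigma525 <= band[2]), 0.95)

  # a ramp inflates the estimate above the true noise sd
  set.seed(13)
  nz <- estimate_noise(mk(10 * times + rnorm(200, 0, 5)), "X1", 20)
  expect_true(all(nz$sigma525 >= 5 * 0.6))
  expect_gt(mean(nz$sigma525), 5)

  expect_error(estimate_noise(mk(rep(1, 200)), "X1", 300),
               class = "platemix_domain_error")
})

test_that("bayes pipeline error bars cover the generator's truth", {
  run <- default_run()
  est <- bayes_pipeline(run$corrected, run$ra, run$cal,
                        n_ra = 25, n_g = 200, seed = 1)[["tagged_1"]]
  truth <- truth_per_cell_cal(run)
  expect_gte(mean(abs(est$per_cell_mean - truth) <= 2 * est$per_cell_sd), 0.9)
  expect_true(all(est$per_cell_sd >= 0))
  expect_equal(est$diagnostics$dropped, 0)
})

test_that("bayes pipeline is reproducible and invariant to well order", {
  run <- default_run()
  a <- bayes_pipeline(run$corrected, run$ra, run$cal, n_ra = 10, n_g = 100,
                      seed = 4)[["tagged_1"]]
  b <- bayes_pipeline(run$corrected, run$ra, run$cal, n_ra = 10, n_g = 100,
                      seed = 4)[["tagged_1"]]
  expect_identical(a$per_cell_mean, b$per_cell_mean)
  expect_identical(a$per_cell_sd, b$per_cell_sd)

  # permute well columns: pooled moments must not change
  perm <- run$corrected
  ord <- rev(seq_len(ncol(perm$od)))
  for (ch in c("od", "f525", "f585")) perm[[ch]] <- perm[[ch]][, ord]
  perm$layout <- perm$layout[rev(seq_len(nrow(perm$layout))), ]
  p <- bayes_pipeline(perm, run$ra, run$cal, n_ra = 10, n_g = 100,
                      seed = 4)[["tagged_1"]]
  expect_equal(p$per_cell_mean, a$per_cell_mean)
  expect_equal(p$per_cell_sd, a$per_cell_sd)
})

test_that("error bars shrink and the mean approaches the direct estimate as noise vanishes", {
  # A near-stationary culture with constant expression: the windowed channel
  # noise estimate then reflects measurement noise rather than the signal's
  # trend, so the property "less noise, smaller error bars" is well-posed.
  # (On a steep induction ramp the windowed estimate saturates at the
  # trend's contribution whatever the true noise.)
  base <- list(od = 0.003, f525 = 2, f585 = 2)
  sds <- list()
  for (scale in c(1, 0.3, 0.03)) {
    sc <- synthetic_scenario(
      growth = list(d0_wildtype = 1.1, d0_tagged = 1.1, rate = 0.35,
                    capacity = 1.2, rate_cv = 0.01),
      expression = list(type = "constant", gmax = 500, t_on = 0, tau = 1),
      noise_sd = lapply(base, function(v) v * scale),
      seed = 29)
    sim <- generate_experiment(sc, n_media = 2, n_wildtype = 2, n_tagged = 2,
                               n_timepoints = 60, dt_h = 0.33)
    corr <- apply_media_correction(sim$dataset, fit_media(sim$dataset))
    # the calibration experiment's measurement noise scales down too,
    # otherwise its (fixed) uncertainty floors the per-cell error bars
    dil <- generate_dilution_series(noise_cv = 0.01 * scale)
    cal <- fit_od_calibration(dil$table$od, dil$table$dilution_factor,
                              noise_cv = max(0.01 * scale, 1e-4))
    ra <- fit_ra(corr)
    est <- bayes_pipeline(corr, ra, cal, n_ra = 15, n_g = 150,
                          seed = 2)[["tagged_1"]]
    sds[[as.character(scale)]] <- est$per_cell_sd
    if (scale == 0.03) {
      dir <- direct_pipeline(corr, cal, smooth = FALSE)[["tagged_1"]]
      expect_lt(stats::median(abs(est$per_cell_mean - dir$per_cell_mean) /
                                pmax(abs(dir$per_cell_mean), 1)), 0.05)
      expect_lt(stats::median(est$per_cell_sd / abs(est$per_cell_mean)), 0.05)
    }
  }
  # a few points may flip by Monte-Carlo jitter where sds nearly coincide
  expect_gte(mean(sds[["0.3"]] < sds[["1"]]), 0.9)
  expect_gte(mean(sds[["0.03"]] < sds[["0.3"]]), 0.9)
})

test_that("doubling the number of g draws leaves the mean stable", {
  run <- default_run()
  a <- bayes_pipeline(run$corrected, run$ra, run$cal, n_ra = 20, n_g = 500,
                      seed = 6)[["tagged_1"]]
  b <- bayes_pipeline(run$corrected, run$ra, run$cal, n_ra = 20, n_g = 1000,
                      seed = 6)[["tagged_1"]]
  expect_true(all(abs(a$per_cell_mean - b$per_cell_mean) <=
                    0.5 * pmax(a$per_cell_sd, 1e-9)))
})
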