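# Spectral unmixing: estimation of the autofluorescence emission ratio
# r_a(OD) from wild-type wells, direct point-estimate unmixing, and the
# bacterial per-OD subtraction baseline kept for comparison.
#
# Measurement model, per tagged well and time point:
#   f525 = g + a
#   f585 = rg * g + ra * a
# where g is reporter fluorescence at 525 nm, a cellular autofluorescence at
# 525 nm, rg the reporter's spectral constant, and ra the autofluorescence
# emission ratio shared by tagged and wild-type cells at equal OD.

new_fluor_estimate <- function(times, g_mean, g_sd, per_cell_mean, per_cell_sd,
                               method, flags = list(), group = NA_character_,
                               strain = NA_character_, condition = NA_character_,
                               n_replicates = NA_integer_, diagnostics = list()) {
  structure(list(
    times = times, g_mean = g_mean, g_sd = g_sd,
    per_cell_mean = per_cell_mean, per_cell_sd = per_cell_sd,
    method = method, flags = flags, replicate_group = group,
    strain = strain, condition = condition, n_replicates = n_replicates,
    diagnostics = diagnostics
  ), class = "fluor_estimate")
}

#' @export
print.fluor_estimate <- function(x, ...) {
  cat(sprintf("<fluor_estimate> %s | group %s | %d time points\n",
              x$method, x$replicate_group, length(x$times)))
  rng <- range(x$per_cell_mean, na.rm = TRUE)
  cat(sprintf("  per-cell fluorescence %.3g to %.3g a.u.\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
as.data.frame.fluor_estimate <- function(x, ...) {
  data.frame(
    strain = x$strain, condition = x$condition, time_h = x$times,
    fl_per_cell_mean = x$per_cell_mean,
    fl_per_cell_sd = if (all(is.na(x$per_cell_sd))) NA_real_ else x$per_cell_sd,
    n_replicates = x$n_replicates, method = x$method,
    stringsAsFactors = FALSE
  )
}

tagged_groups <- function(dataset) {
  lay <- dataset$layout
  split(lay$well[lay$role == "tagged"],
        lay$replicate_group[lay$role == "tagged"])
}

#' Estimate the autofluorescence emission ratio as a function of OD
#'
#' Forms the pointwise ratio `f585 / f525` for every wild-type well and time
#' point of a media-corrected dataset, orders the ratios by media-corrected
#' OD, and fits a Gaussian process with a neural-network covariance (whose
#' samples are sigmoid-like, matching how the ratio rises with OD in yeast).
#' The measurement error of the ratio changes with OD, so it is estimated
#' empirically at each point as the standard deviation of the `k` nearest
#' points along OD, and those noise magnitudes are themselves fitted against
#' OD with a squared-exponential GP so they can later be interpolated to the
#' tagged strain's ODs.
#'
#' A ratio with a noisy denominator is biased upward
#' (`E[f585/f525] ~ ra (1 + cv^2)` with `cv = s525/f525`), which matters at
#' low OD where autofluorescence is weak; each ratio therefore carries a
#' first-order (Beale-type) bias correction, with the denominator's noise
#' estimated trend-robustly from first differences in time so that growth
#' does not inflate it.
#'
#' @param dataset A media-corrected [plate_dataset()] with wild-type wells.
#' @param k Neighbourhood size for the empirical noise estimate (capped at
#'   the number of usable points).
#' @param bias_correct Apply the ratio bias correction (default `TRUE`).
#' @return An object of class `ra_curve`: `gp` (ratio vs OD, fitted after
#'   centring and restored on prediction via the stored `offset`),
#'   `noise_interp` (noise sd vs OD), and `od_support` (range of wild-type
#'   ODs used).
#' @export
fit_ra <- function(dataset, k = 20, bias_correct = TRUE) {
  stopifnot(inherits(dataset, "plate_dataset"))
  wt <- wells_by_role(dataset, "wildtype")
  if (length(wt) == 0) {
    stop_platemix("no wild-type wells in layout", "platemix_layout_error")
  }
  od <- numeric(0); ratio <- numeric(0)
  for (w in wt) {
    f525 <- dataset$f525[, w]; f585 <- dataset$f585[, w]
    r <- f585 / f525
    if (bias_correct) {
      d <- diff(f525)
      nd <- empirical_noise(dataset$times[-1], d, min(20, length(d))) / sqrt(2)
      s525 <- c(nd[1], nd)
      r <- r / (1 + (s525 / f525)^2)
    }
    od <- c(od, dataset$od[, w]); ratio <- c(ratio, r)
    usable_w <- f525 > 0
    if (any(!usable_w)) {
      warning(sprintf("excluding %d point(s) of well %s with f525 <= 0 after media correction",
                      sum(!usable_w), w), call. = FALSE)
      od <- od[c(rep(TRUE, length(od) - length(f525)), usable_w)]
      ratio <- ratio[c(rep(TRUE, length(ratio) - length(f525)), usable_w)]
    }
  }
  if (length(od) < 4) {
    stop_platemix("too few usable wild-type points to estimate the emission ratio",
                  "platemix_estimation_error")
  }
  ord <- order(od)
  od <- od[ord]; ratio <- ratio[ord]

  k_eff <- min(k, length(od))
  noise <- empirical_noise(od, ratio, k_eff)
  offset <- mean(ratio)
  gp <- gp_fit(od, ratio - offset, noise,
               kernel_nn(max(stats::sd(ratio), 0.05), 1, 1 / max(stats::sd(od), 0.1)))
  noise_gp <- gp_fit(od, noise, "learn",
                     kernel_sqexp(max(stats::sd(noise), 1e-4),
                                  diff(range(od)) / 2))
  structure(list(gp = gp, offset = offset, noise_interp = noise_gp,
                 od_support = range(od)),
            class = "ra_curve")
}

#' Evaluate and sample the emission-ratio curve at the tagged strain's ODs
#'
#' The tagged strain grows along its own OD trajectory, so the ratio must be
#' evaluated at *its* ODs, not the wild-type's. Returns the posterior mean,
#' joint posterior sample functions of the latent ratio curve, and the
#' measurement-error sd interpolated to those ODs via the fitted noise GP.
#'
#' The sampled curves represent uncertainty about the smooth underlying
#' ratio; the pointwise measurement error of individual wild-type ratios has
#' already shaped that posterior through the heteroscedastic fit. Setting
#' `include_noise = TRUE` additionally adds independent Gaussian noise with
#' the interpolated sd to each sampled curve (posterior-predictive draws of
#' ratio *measurements*); this is kept selectable but is off by default
#' because where the ratio is poorly measured a noisy draw can fall near the
#' reporter constant and make the unmixing singular.
#'
#' @param ra An [fit_ra()] result.
#' @param od Numeric vector of tagged-strain (media-corrected) ODs.
#' @param n_samples Number of sample functions.
#' @param seed Integer seed.
#' @param include_noise Add interpolated measurement noise to the samples.
#' @return List with `mean`, `samples` (a `length(od)` by `n_samples`
#'   matrix), `noise_sd`, and logical `extrapolated` flags for ODs outside
#'   the wild-type support.
#' @export
ra_at <- function(ra, od, n_samples, seed, include_noise = FALSE) {
  stopifnot(inherits(ra, "ra_curve"))
  assert_numeric(od, "od")
  mu <- gp_predict(ra$gp, od)$mean + ra$offset
  noise_sd <- pmax(gp_predict(ra$noise_interp, od)$mean, 1e-12)
  samples <- gp_sample(ra$gp, od, n_samples, seed) + ra$offset
  if (include_noise) {
    eps <- with_seed(derive_seed(seed, 1L),
                     matrix(stats::rnorm(length(od) * n_samples, 0, noise_sd),
                            nrow = length(od)))
    samples <- samples + eps
  }
  list(mean = mu, samples = samples, noise_sd = noise_sd,
       extrapolated = od < ra$od_support[1] | od > ra$od_support[2])
}

#' Solve the two-channel mixing model for the reporter signal
#'
#' Inverts `f525 = g + a`, `f585 = rg g + ra a` for `g`:
#' `g = (ra f525 - f585) / (ra - rg)`. Negative results are legitimate
#' point estimates (measurement noise around zero expression) and are
#' reported, not clipped.
#'
#' @param f525,f585 Media-corrected fluorescence at 525 and 585 nm.
#' @param ra Autofluorescence emission ratio at the well's OD.
#' @param rg Reporter emission ratio (EGFP: 0.114).
#' @return The reporter fluorescence `g` at 525 nm (vectorized).
#' @export
direct_unmix <- function(f525, f585, ra, rg) {
  if (any(abs(ra - rg) < 1e-6)) {
    stop_platemix("unmixing is ill-conditioned: |ra - rg| < 1e-6",
                  "platemix_illconditioned_error")
  }
  (ra * f525 - f585) / (ra - rg)
}

# Local quadratic regression with tricube weights and robustness
# reweighting (Matlab's "rloess"); surface = "direct" keeps it exact. The
# span is widened on short series so each local fit sees at least 7 points
# (a quadratic with fewer is ill-conditioned).
loess_smooth <- function(x, y, span = 0.15, enable = TRUE) {
  if (!enable) return(y)
  span <- max(span, min(7 / length(x), 1))
  fit <- stats::loess(y ~ x, span = span, degree = 2, family = "symmetric",
                      control = stats::loess.control(surface = "direct",
                                                     iterations = 2))
  stats::predict(fit, x)
}

#' Direct (point-estimate) unmixing pipeline
#'
#' The straightforward estimator: no error bars, but fast and transparent.
#' Per time point, the emission ratio is the mean of `f585/f525` over
#' wild-type replicates; the replicate-averaged wild-type OD curve is
#' smoothed by local quadratic regression and made monotone by isotonic
#' projection, giving a one-to-one OD-time correspondence through which the
#' ratio is looked up at each tagged OD (ODs beyond the monotone wild-type
#' range reuse the boundary value and are flagged). The mixing model is then
#' inverted per replicate, averaged, smoothed, and divided by the calibrated
#' relative cell density.
#'
#' @param dataset A media-corrected [plate_dataset()] with wild-type and
#'   tagged wells.
#' @param cal An [fit_od_calibration()] (or [identity_calibration()]).
#' @param constants [unmixing_constants()].
#' @param span Local-regression span (fraction of points).
#' @param smooth Disable to obtain the raw unsmoothed estimator (exact on
#'   noiseless data).
#' @return Named list of `fluor_estimate` objects, one per tagged replicate
#'   group.
#' @export
direct_pipeline <- function(dataset, cal, constants = unmixing_constants(),
                            span = 0.15, smooth = TRUE) {
  stopifnot(inherits(dataset, "plate_dataset"), inherits(cal, "od_calibration"))
  wt <- wells_by_role(dataset, "wildtype")
  groups <- tagged_groups(dataset)
  if (length(wt) == 0 || length(groups) == 0) {
    stop_platemix("direct pipeline needs wild-type and tagged wells",
                  "platemix_layout_error")
  }
  times <- dataset$times
  ratio_wt <- dataset$f585[, wt, drop = FALSE] / dataset$f525[, wt, drop = FALSE]
  ra_t <- rowMeans(ratio_wt)
  od_wt <- rowMeans(dataset$od[, wt, drop = FALSE])
  od_wt_s <- loess_smooth(times, od_wt, span, smooth)
  od_wt_mono <- stats::isoreg(times, od_wt_s)$yf

  lapply_named(groups, function(group_wells, group_name) {
    od_tag <- dataset$od[, group_wells, drop = FALSE]
    od_tag_mean <- rowMeans(od_tag)
    ra_lookup <- stats::approx(od_wt_mono, ra_t, xout = od_tag_mean,
                               rule = 2, ties = mean)$y
    extrap <- od_tag_mean < min(od_wt_mono) | od_tag_mean > max(od_wt_mono)
    g_reps <- vapply(group_wells, function(w) {
      direct_unmix(dataset$f525[, w], dataset$f585[, w], ra_lookup, constants$rg)
    }, numeric(length(times)))
    g_mean <- rowMeans(g_reps)
    g_s <- loess_smooth(times, g_mean, span, smooth)
    dens <- correct_od(cal, od_tag_mean)
    lay <- dataset$layout[match(group_wells[1], dataset$layout$well), ]
    new_fluor_estimate(
      times = times, g_mean = g_s, g_sd = rep(NA_real_, length(times)),
      per_cell_mean = g_s / dens$density_mean,
      per_cell_sd = rep(NA_real_, length(times)),
      method = "direct",
      flags = list(ra_extrapolated = extrap,
                   od_extrapolated = dens$extrapolated,
                   negative = g_s < 0),
      group = group_name, strain = lay$strain, condition = lay$condition,
      n_replicates = length(group_wells)
    )
  })
}

#' Per-OD subtraction baseline (bacterial method)
#'
#' The correction used for *E. coli* promoter fusions: subtract the
#' wild-type's fluorescence per unit cell density from the tagged strain's,
#' at matching time points. It assumes equal autofluorescence per cell and
#' equal growth in both strains — assumptions that fail in yeast, where this
#' estimator can go systematically negative for weakly expressed proteins.
#' Provided for comparison plots and tests only.
#'
#' @inheritParams direct_pipeline
#' @return Named list of `fluor_estimate` objects per tagged replicate group.
#' @export
subtraction_baseline <- function(dataset, cal) {
  stopifnot(inherits(dataset, "plate_dataset"), inherits(cal, "od_calibration"))
  wt <- wells_by_role(dataset, "wildtype")
  groups <- tagged_groups(dataset)
  if (length(wt) == 0 || length(groups) == 0) {
    stop_platemix("subtraction baseline needs wild-type and tagged wells",
                  "platemix_layout_error")
  }
  times <- dataset$times
  percell_well <- function(w) {
    od <- dataset$od[, w]
    ok <- od > 0
    dens <- correct_od(cal, od)$density_mean
    out <- ifelse(ok, dataset$f525[, w] / dens, NA_real_)
    out
  }
  wt_percell <- rowMeans(vapply(wt, percell_well, numeric(length(times))),
                         na.rm = TRUE)
  lapply_named(groups, function(group_wells, group_name) {
    tag <- rowMeans(vapply(group_wells, percell_well, numeric(length(times))),
                    na.rm = TRUE)
    per_cell <- tag - wt_percell
    lay <- dataset$layout[match(group_wells[1], dataset$layout$well), ]
    new_fluor_estimate(
      times = times, g_mean = rep(NA_real_, length(times)),
      g_sd = rep(NA_real_, length(times)),
      per_cell_mean = per_cell, per_cell_sd = rep(NA_real_, length(times)),
      method = "subtraction",
      flags = list(skipped = !is.finite(per_cell), negative = per_cell < 0),
      group = group_name, strain = lay$strain, condition = lay$condition,
      n_replicates = length(group_wells)
    )
  })
}

lapply_named <- function(x, f) {
  out <- lapply(seq_along(x), function(i) f(x[[i]], names(x)[i]))
  names(out) <- names(x)
  out
}
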