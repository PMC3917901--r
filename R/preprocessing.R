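# Media background correction and OD -> relative-cell-density calibration.

#' Fit smooth media baselines over time
#'
#' Pools every media-blank well and fits, per channel (OD, f525, f585), a
#' squared-exponential Gaussian process over time. Plate and media background
#' drifts slowly during an experiment, so a constant blank is not enough.
#' Measurement error is estimated per point as the standard deviation of the
#' 10 nearest-in-time pooled points ([empirical_noise()]); if the
#' heteroscedastic fit's optimizer fails to converge, the channel is refitted
#' with a single constant noise scale learned jointly with the
#' hyperparameters, and `mode_used` records which path succeeded.
#'
#' @param dataset A [plate_dataset()] with at least one media well.
#' @param noise_k Neighbourhood size for the empirical noise estimate.
#' @return An object of class `media_correction`: per-channel `gp_posterior`
#'   baselines over time and a `mode_used` flag per channel
#'   (`"heteroscedastic"` or `"constant_noise"`).
#' @export
fit_media <- function(dataset, noise_k = 10) {
  stopifnot(inherits(dataset, "plate_dataset"))
  media <- wells_by_role(dataset, "media")
  if (length(media) == 0) {
    stop_platemix("no media wells in layout", "platemix_layout_error")
  }
  tt <- rep(dataset$times, times = length(media))
  fit_channel <- function(channel) {
    y <- as.vector(dataset[[channel]][, media, drop = FALSE])
    offset <- mean(y)            # GP is zero-mean; fit the deviation
    yc <- y - offset
    k <- min(noise_k, length(y))
    ns <- empirical_noise(tt, yc, k)
    kern <- kernel_sqexp(max(stats::sd(y), 1e-6), diff(range(tt)) / 4)
    post <- tryCatch(
      list(gp = gp_fit(tt, yc, ns, kern), mode = "heteroscedastic"),
      platemix_fit_error = function(e) NULL,
      platemix_numerical_error = function(e) NULL
    )
    if (is.null(post)) {
      post <- list(gp = gp_fit(tt, yc, "learn", kern), mode = "constant_noise")
    }
    post$offset <- offset
    post
  }
  ch <- lapply(c(od = "od", f525 = "f525", f585 = "f585"), fit_channel)
  structure(list(
    od_baseline = ch$od$gp, f525_baseline = ch$f525$gp,
    f585_baseline = ch$f585$gp,
    offsets = vapply(ch, function(x) x$offset, numeric(1)),
    mode_used = vapply(ch, function(x) x$mode, character(1)),
    time_range = range(dataset$times)
  ), class = "media_correction")
}

#' Media baseline posterior means at given times
#'
#' @param mc A [fit_media()] result.
#' @param times Numeric vector of times (hours).
#' @return List with numeric vectors `od`, `f525`, `f585`.
#' @export
media_baseline <- function(mc, times) {
  stopifnot(inherits(mc, "media_correction"))
  list(
    od = gp_predict(mc$od_baseline, times)$mean + mc$offsets[["od"]],
    f525 = gp_predict(mc$f525_baseline, times)$mean + mc$offsets[["f525"]],
    f585 = gp_predict(mc$f585_baseline, times)$mean + mc$offsets[["f585"]]
  )
}

#' Subtract media baselines from all cell wells
#'
#' Subtracts each channel's baseline posterior mean, evaluated at the
#' dataset's time grid, from every non-media well, and drops the media wells
#' from the result. Corrected values may be negative (they are never
#' clipped); the number of negative values per well and channel is recorded
#' in the returned dataset's `meta$qc_negative`.
#'
#' @param dataset A [plate_dataset()].
#' @param mc A [fit_media()] result whose baselines cover the dataset's time
#'   range.
#' @return A new `plate_dataset` without media wells.
#' @export
apply_media_correction <- function(dataset, mc) {
  stopifnot(inherits(dataset, "plate_dataset"), inherits(mc, "media_correction"))
  keep <- dataset$layout$well[dataset$layout$role != "media"]
  base <- media_baseline(mc, dataset$times)
  out <- dataset
  qc <- list()
  for (channel in c("od", "f525", "f585")) {
    m <- dataset[[channel]][, keep, drop = FALSE] - base[[channel]]
    out[[channel]] <- m
    qc[[channel]] <- colSums(m < 0)
  }
  out$layout <- dataset$layout[dataset$layout$role != "media", , drop = FALSE]
  out$meta$qc_negative <- qc
  out$meta$media_corrected <- TRUE
  out
}

#' Calibrate measured OD against relative cell density
#'
#' Fits the monotone map from measured OD to relative cell density using a
#' doubling-dilution series: relative density is `1 / dilution_factor`,
#' scaled so that the most concentrated sample has density 1.0. The
#' regression is a Gaussian process whose covariance is the sum of a squared
#' exponential and a linear kernel — smooth, increasing functions whose
#' extrapolation beyond the calibrated range stays sane thanks to the linear
#' component.
#'
#' Because dilution factors are known exactly, the dominant error is the
#' multiplicative OD measurement error, which induces an approximately
#' proportional error on the density axis; the default noise model is
#' therefore heteroscedastic with sd = `noise_cv` x density (floored), rather
#' than a single constant; the default 1% matches typical plate-reader OD
#' repeatability.
#'
#' @param measured_od Measured OD of each dilution.
#' @param dilution_factor Known dilution factors (e.g. 1, 2, 4, ..., 256).
#' @param noise_cv Coefficient of variation of the density-scale noise model;
#'   set `noise_cv = "learn"` to learn a constant noise instead.
#' @param absolute_anchor Optional numeric of length 2, `(relative density,
#'   cells/mL)`, stored as metadata only (e.g. `c(1.0, 1.46e7)` from a
#'   hemocytometer count).
#' @return An object of class `od_calibration` with the fitted `gp`, the
#'   calibrated `od_range`, and the anchor.
#' @export
fit_od_calibration <- function(measured_od, dilution_factor, noise_cv = 0.01,
                               absolute_anchor = NULL) {
  assert_numeric(measured_od, "measured_od")
  assert_numeric(dilution_factor, "dilution_factor")
  if (length(measured_od) < 4) {
    stop_platemix("need at least 4 dilution points", "platemix_domain_error")
  }
  if (length(measured_od) != length(dilution_factor) || any(dilution_factor <= 0)) {
    stop_platemix("dilution factors must be positive and match measured_od",
                  "platemix_domain_error")
  }
  density <- (1 / dilution_factor) / max(1 / dilution_factor)
  kern <- kernel_sum(
    kernel_sqexp(max(stats::sd(density), 0.1), diff(range(measured_od)) / 2),
    kernel_linear(1)
  )
  noise <- if (identical(noise_cv, "learn")) "learn" else
    pmax(noise_cv * density, 1e-4)
  gp <- gp_fit(measured_od, density, noise, kern)

  od_range <- range(measured_od)
  grid <- seq(od_range[1], od_range[2], length.out = 200)
  mu <- gp_predict(gp, grid)$mean
  if (any(diff(mu) < -1e-8 * diff(range(mu)))) {
    stop_platemix(paste("calibration posterior mean is not monotone over the",
                        "OD range; collect more dilution points or restrict the range"),
                  "platemix_calibration_error")
  }
  structure(list(gp = gp, od_range = od_range,
                 absolute_anchor = absolute_anchor),
            class = "od_calibration")
}

#' Identity OD calibration
#'
#' Used when no dilution series is available: relative density is taken equal
#' to measured OD, with a prominent warning, so that downstream code runs on
#' raw OD in a degraded but honest mode.
#'
#' @param od_range Numeric length-2 range over which the identity map is
#'   declared calibrated.
#' @return An `od_calibration`.
#' @export
identity_calibration <- function(od_range = c(0, 2)) {
  warning(paste("no OD calibration supplied: using relative density = OD;",
                "per-cell values will inherit any OD nonlinearity"),
          call. = FALSE)
  grid <- seq(od_range[1] + 1e-3, od_range[2], length.out = 25)
  gp <- gp_fit(grid, grid, rep(1e-6, length(grid)),
               kernel_linear(1), optimize = TRUE)
  structure(list(gp = gp, od_range = od_range, absolute_anchor = NULL),
            class = "od_calibration")
}

#' Map measured OD to relative cell density
#'
#' @param cal An [fit_od_calibration()] result.
#' @param od Numeric vector of (media-corrected) measured ODs.
#' @return List with `density_mean`, `density_sd`, and a logical
#'   `extrapolated` flag for ODs outside the calibrated range.
#' @export
correct_od <- function(cal, od) {
  stopifnot(inherits(cal, "od_calibration"))
  assert_numeric(od, "od")
  pr <- gp_predict(cal$gp, od)
  list(density_mean = pr$mean, density_sd = pr$sd,
       extrapolated = od < cal$od_range[1] | od > cal$od_range[2])
}
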