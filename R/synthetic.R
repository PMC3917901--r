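# Forward-model generator of complete synthetic plate experiments with known
# ground truth. Measured signals follow the linear mixing model
#   f525 = g + a,   f585 = rg * g + ra(OD) * a,
# on top of a slowly drifting media background, with logistic growth, a
# saturating density -> OD map, and independent Gaussian measurement noise.

#' Define a synthetic plate-experiment scenario
#'
#' The defaults emulate a budding-yeast induction experiment: cultures start
#' near OD 0.25 (wild-type) / 0.3 (tagged, higher so that its OD range is
#' covered by the wild-type's from the start is *not* guaranteed — the real
#' design starts wild-type lower for exactly that reason), grow logistically
#' to a plateau near OD 1.3 over ~20 h sampled every 12 minutes, the
#' autofluorescence emission ratio rises sigmoidally from about 0.4 to 0.6
#' across the OD range, and reporter expression turns on after a delay and
#' plateaus. OD saturates as a compressive function of cell density, with the
#' deviation from linearity beginning around OD 0.5.
#'
#' @param growth List: `d0_wildtype`, `d0_tagged` (initial relative cell
#'   densities), `rate` (per hour), `capacity` (relative density), `rate_cv`
#'   (well-to-well lognormal growth-rate variation).
#' @param od_map List: `slope` (OD per relative-density unit at low density)
#'   and `shoulder` (density scale where compression sets in); the map is
#'   `od(d) = slope * shoulder * log1p(d / shoulder)`.
#' @param ra_profile List: either `type = "constant"` with `value`, or
#'   `type = "sigmoid"` with `lo`, `hi`, `midpoint`, `width` (in OD units).
#' @param autofl_per_cell List: `wildtype`, `tagged` (a.u. per relative
#'   density unit) and `od_slope` (fractional change per OD unit).
#' @param expression List: `type` one of `"off"`, `"constant"`,
#'   `"induction"`; `gmax` (a.u. per relative density unit), `t_on`, `tau`
#'   (hours) for the induction ramp.
#' @param media_drift List of linear background drifts per channel:
#'   `od0`, `od_slope`, `f525_0`, `f525_slope`, `f585_0`, `f585_slope`.
#' @param noise_sd List of per-channel Gaussian measurement noise standard
#'   deviations: `od`, `f525`, `f585`.
#' @param rg_true Reporter emission ratio used by the forward model.
#' @param seed Integer seed making the generated experiment reproducible.
#' @return An object of class `synthetic_scenario`.
#' @seealso [generate_experiment()], [generate_dilution_series()]
#' @export
synthetic_scenario <- function(
    growth = list(d0_wildtype = 0.10, d0_tagged = 0.12, rate = 0.35,
                  capacity = 1.2, rate_cv = 0.02),
    od_map = list(slope = 2.5, shoulder = 0.37),
    ra_profile = list(type = "sigmoid", lo = 0.4, hi = 0.6,
                      midpoint = 0.6, width = 0.15),
    autofl_per_cell = list(wildtype = 100, tagged = 100, od_slope = 0),
    expression = list(type = "induction", gmax = 500, t_on = 2, tau = 2),
    media_drift = list(od0 = 0.04, od_slope = 5e-4,
                       f525_0 = 30, f525_slope = 0.2,
                       f585_0 = 15, f585_slope = 0.1),
    noise_sd = list(od = 0.003, f525 = 2, f585 = 2),
    rg_true = 0.114,
    seed = 1L) {
  sc <- structure(list(
    growth = growth, od_map = od_map, ra_profile = ra_profile,
    autofl_per_cell = autofl_per_cell, expression = expression,
    media_drift = media_drift, noise_sd = noise_sd,
    rg_true = rg_true, seed = as.integer(seed)
  ), class = "synthetic_scenario")
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  g <- sc$growth
  if (g$capacity <= 0 || g$rate <= 0 || g$d0_wildtype <= 0 || g$d0_tagged <= 0) {
    stop_platemix("growth parameters must be strictly positive",
                  "platemix_validation_error")
  }
  if (sc$od_map$slope <= 0 || sc$od_map$shoulder <= 0) {
    stop_platemix("od_map parameters must be strictly positive",
                  "platemix_validation_error")
  }
  if (any(unlist(sc$noise_sd) < 0)) {
    stop_platemix("noise_sd must be non-negative", "platemix_validation_error")
  }
  if (sc$rg_true < 0 || sc$rg_true >= 1) {
    stop_platemix("rg_true must be in [0, 1)", "platemix_validation_error")
  }
  invisible(sc)
}

# Closures realizing the scenario's parameterized curves.
scenario_functions <- function(sc) {
  om <- sc$od_map
  od_map <- function(d) om$slope * om$shoulder * log1p(d / om$shoulder)
  rp <- sc$ra_profile
  ra_profile <- if (identical(rp$type, "constant")) {
    function(od) rep(rp$value, length(od))
  } else {
    function(od) rp$lo + (rp$hi - rp$lo) / (1 + exp(-(od - rp$midpoint) / rp$width))
  }
  af <- sc$autofl_per_cell
  autofl <- function(od, strain_role) {
    base <- if (identical(strain_role, "tagged")) af$tagged else af$wildtype
    base * (1 + af$od_slope * od)
  }
  ex <- sc$expression
  expr_per_cell <- switch(ex$type,
    off = function(t) rep(0, length(t)),
    constant = function(t) rep(ex$gmax, length(t)),
    induction = function(t) ex$gmax * pmax(0, 1 - exp(-(t - ex$t_on) / ex$tau)) *
      (t >= ex$t_on),
    stop_platemix("unknown expression type", "platemix_validation_error")
  )
  md <- sc$media_drift
  list(
    od_map = od_map, ra_profile = ra_profile, autofl = autofl,
    expr_per_cell = expr_per_cell,
    media = list(
      od = function(t) md$od0 + md$od_slope * t,
      f525 = function(t) md$f525_0 + md$f525_slope * t,
      f585 = function(t) md$f585_0 + md$f585_slope * t
    )
  )
}

logistic_density <- function(t, d0, rate, capacity) {
  capacity * d0 * exp(rate * t) / (capacity + d0 * (exp(rate * t) - 1))
}

#' Generate a synthetic plate experiment with ground truth
#'
#' @param scenario A [synthetic_scenario()].
#' @param n_media,n_wildtype,n_tagged Number of wells per role (media and
#'   wild-type at least 1).
#' @param n_timepoints Number of time points (>= 25).
#' @param dt_h Sampling interval, hours.
#' @return A list with `dataset` (a [plate_dataset()]) and `truth`, a list
#'   holding per-well true relative density, autofluorescence `a`, reporter
#'   signal `g`, and per-cell fluorescence `g / density` (all aligned with the
#'   dataset's time grid), plus the scenario's `ra_profile` and `od_map`
#'   closures.
#' @export
generate_experiment <- function(scenario, n_media = 3, n_wildtype = 3,
                                n_tagged = 3, n_timepoints = 100, dt_h = 0.2) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (n_media < 1 || n_wildtype < 1 || n_tagged < 0) {
    stop_platemix("need at least one media and one wild-type well",
                  "platemix_validation_error")
  }
  if (n_timepoints < 25) {
    stop_platemix("n_timepoints must be >= 25", "platemix_validation_error")
  }
  fn <- scenario_functions(scenario)
  times <- (seq_len(n_timepoints) - 1) * dt_h
  g <- scenario$growth

  wells <- c(paste0("M", seq_len(n_media)),
             paste0("W", seq_len(n_wildtype)),
             if (n_tagged > 0) paste0("T", seq_len(n_tagged)))
  roles <- c(rep("media", n_media), rep("wildtype", n_wildtype),
             rep("tagged", n_tagged))

  out <- with_seed(scenario$seed, {
    rate_jit <- exp(stats::rnorm(length(wells), 0, g$rate_cv))
    rows <- vector("list", length(wells))
    truth_wells <- vector("list", length(wells))
    for (i in seq_along(wells)) {
      role <- roles[i]
      if (role == "media") {
        d <- rep(0, n_timepoints); a <- rep(0, n_timepoints)
        gg <- rep(0, n_timepoints); od_cells <- rep(0, n_timepoints)
        ra <- rep(NA_real_, n_timepoints)
      } else {
        d0 <- if (role == "wildtype") g$d0_wildtype else g$d0_tagged
        d <- logistic_density(times, d0, g$rate * rate_jit[i], g$capacity)
        od_cells <- fn$od_map(d)
        ra <- fn$ra_profile(od_cells)
        a <- fn$autofl(od_cells, role) * d
        gg <- if (role == "tagged") fn$expr_per_cell(times) * d else rep(0, n_timepoints)
      }
      ns <- scenario$noise_sd
      od_meas <- od_cells + fn$media$od(times) +
        stats::rnorm(n_timepoints, 0, ns$od)
      f525 <- gg + a + fn$media$f525(times) +
        stats::rnorm(n_timepoints, 0, ns$f525)
      f585 <- scenario$rg_true * gg + ifelse(is.na(ra), 0, ra) * a +
        fn$media$f585(times) + stats::rnorm(n_timepoints, 0, ns$f585)
      rows[[i]] <- data.frame(well = wells[i], time_h = times,
                              od = od_meas, f525 = f525, f585 = f585,
                              stringsAsFactors = FALSE)
      truth_wells[[i]] <- list(
        density = d, a = a, g = gg,
        per_cell = ifelse(d > 0, gg / d, 0),
        od_cells = od_cells, ra = ra
      )
    }
    list(rows = rows, truth_wells = truth_wells)
  })

  layout <- data.frame(
    well = wells, role = roles,
    strain = ifelse(roles == "media", "",
                    ifelse(roles == "wildtype", "BY4741", "BY4741 GFP-tag")),
    condition = "synthetic",
    replicate_group = ifelse(roles == "tagged", "tagged_1", roles),
    stringsAsFactors = FALSE
  )
  names(out$truth_wells) <- wells
  list(
    dataset = plate_dataset(do.call(rbind, out$rows), layout,
                            meta = list(source = "synthetic")),
    truth = list(times = times, wells = out$truth_wells,
                 ra_profile = fn$ra_profile, od_map = fn$od_map,
                 scenario = scenario)
  )
}

#' Generate a synthetic doubling-dilution calibration series
#'
#' Emulates the bench calibration in which a dense culture is diluted in
#' doubling steps (1x, 2x, 4x, ...) and the OD of each dilution is measured:
#' the most concentrated sample defines relative cell density 1.0.
#'
#' @param od_map Function mapping relative cell density to true OD (e.g. from
#'   `scenario_functions`); defaults to the default scenario's map.
#' @param n_dilutions Number of doubling dilutions (>= 4); 9 gives the 1x-256x
#'   design.
#' @param noise_cv Multiplicative coefficient of variation of the measured OD.
#' @param seed Integer seed.
#' @param top_density True relative density of the undiluted sample. The
#'   default, 1.2, is the default scenario's carrying capacity: the
#'   calibration culture is grown to saturation before dilution, so the
#'   calibrated OD range spans the ODs reached in the experiment. (On the
#'   calibrated scale, per-cell fluorescence is expressed per
#'   `top_density` units of growth-scale density.)
#' @return A list with `table` (data frame `od`, `dilution_factor`) and
#'   `truth` (data frame with the true densities and noiseless ODs).
#' @export
generate_dilution_series <- function(od_map = NULL, n_dilutions = 9,
                                     noise_cv = 0.01, seed = 1L,
                                     top_density = 1.2) {
  if (n_dilutions < 4) {
    stop_platemix("n_dilutions must be >= 4", "platemix_validation_error")
  }
  if (is.null(od_map)) {
    od_map <- scenario_functions(synthetic_scenario())$od_map
  }
  factors <- 2^(seq_len(n_dilutions) - 1)
  density <- top_density / factors
  od_true <- od_map(density)
  od_meas <- with_seed(seed,
    od_true * (1 + stats::rnorm(n_dilutions, 0, noise_cv)))
  list(
    table = data.frame(od = od_meas, dilution_factor = factors),
    truth = data.frame(dilution_factor = factors, density = density,
                       od_true = od_true)
  )
}
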