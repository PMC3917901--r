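# Shared fixtures, built once per test run and cached. All data are
# generated in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Default synthetic experiment, media-corrected, with calibration and fitted
# emission-ratio curve: the workhorse for pipeline tests.
default_run <- function() {
  fixture("default_run", function() {
    sim <- generate_experiment(synthetic_scenario(), n_media = 3,
                               n_wildtype = 3, n_tagged = 3,
                               n_timepoints = 100, dt_h = 0.2)
    mc <- fit_media(sim$dataset)
    corrected <- apply_media_correction(sim$dataset, mc)
    dil <- generate_dilution_series()
    cal <- fit_od_calibration(dil$table$od, dil$table$dilution_factor)
    ra <- fit_ra(corrected)
    list(sim = sim, mc = mc, corrected = corrected, dil = dil, cal = cal,
         ra = ra, top_density = max(dil$truth$density))
  })
}

# Truth helpers on the calibrated density scale (the calibration's undiluted
# sample defines relative density 1.0).
truth_per_cell_cal <- function(run, wells = c("T1", "T2", "T3")) {
  rowMeans(sapply(wells, function(w) run$sim$truth$wells[[w]]$per_cell)) *
    run$top_density
}

truth_density_cal <- function(run, wells = c("T1", "T2", "T3")) {
  rowMeans(sapply(wells, function(w) run$sim$truth$wells[[w]]$density)) /
    run$top_density
}

# Tiny hand-built plate for I/O and validation tests.
tiny_plate <- function() {
  times <- c(0, 0.5, 1, 1.5, 2)
  mkrows <- function(well, od, f525, f585) {
    data.frame(well = well, time_h = times, od = od, f525 = f525, f585 = f585)
  }
  data <- rbind(
    mkrows("A1", 0.04 + times / 100, 30 + times, 15 + times / 2),
    mkrows("A2", 0.2 + times / 10, 50 + 10 * times, 25 + 5 * times),
    mkrows("A3", 0.25 + times / 10, 80 + 20 * times, 30 + 6 * times)
  )
  layout <- data.frame(
    well = c("A1", "A2", "A3"),
    role = c("media", "wildtype", "tagged"),
    strain = c("", "wt", "tag"),
    condition = "2% galactose",
    replicate_group = c("media", "wt", "g1")
  )
  plate_dataset(data, layout)
}

# Independent multivariate-normal log-density (direct solve + determinant),
# used as the evidence oracle: shares no code with the GP module's
# Cholesky-based path.
mvn_logdensity <- function(y, S) {
  n <- length(y)
  -0.5 * drop(t(y) %*% solve(S, y)) -
    0.5 * determinant(S, logarithm = TRUE)$modulus -
    0.5 * n * log(2 * pi)
}
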