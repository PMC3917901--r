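# Bayesian estimation of the reporter signal g with full error propagation.
#
# With a uniform prior on g and the autofluorescence a integrated out over
# the whole real line, the likelihood of g at one time point is proportional
# to a Gaussian in g:
#   P(f525, f585 | ra, rg, g) ~ exp( -(f585 - ra f525 - (rg - ra) g)^2 /
#                                     (2 (s585^2 + ra^2 s525^2)) )
# Sampling g from this density for many sampled r_a curves and OD-correction
# curves, then pooling over replicates, yields the mean fluorescence per cell
# and its error bar.

#' Closed-form parameters of the per-time-point likelihood of g
#'
#' Viewed as a function of `g`, the likelihood is proportional to a Gaussian
#' density with
#' `mu_g = (f585 - ra f525) / (rg - ra)` and
#' `sd_g = sqrt(s585^2 + ra^2 s525^2) / |rg - ra|`.
#' `mu_g` is algebraically identical to [direct_unmix()]; this closed form is
#' the oracle against which the rejection sampler is audited.
#'
#' @param f525,f585 Media-corrected fluorescence values (vectorized).
#' @param ra,rg Emission ratios (autofluorescence, reporter).
#' @param s525,s585 Measurement-error standard deviations of the two
#'   channels.
#' @return List with numeric `mu_g` and `sd_g`.
#' @export
g_likelihood_params <- function(f525, f585, ra, rg, s525, s585) {
  if (any(abs(ra - rg) < 1e-6)) {
    stop_platemix("likelihood is ill-conditioned: |ra - rg| < 1e-6",
                  "platemix_illconditioned_error")
  }
  if (any(s525 <= 0) || any(s585 <= 0)) {
    stop_platemix("measurement-error sds must be strictly positive",
                  "platemix_domain_error")
  }
  list(mu_g = (f585 - ra * f525) / (rg - ra),
       sd_g = sqrt(s585^2 + ra^2 * s525^2) / abs(rg - ra))
}

#' Sample the reporter signal g at one time point
#'
#' Draws from the per-time-point likelihood of `g`. Two samplers are
#' provided: `"rejection"` proposes uniformly over `mu_g +/- 6 sd_g` and
#' accepts against the unnormalized Gaussian kernel (the method as
#' described), and `"gaussian"` draws directly from the closed form of
#' [g_likelihood_params()], which is distributionally identical and much
#' faster. `g` is not truncated at zero: negative draws are legitimate under
#' measurement noise and truncation would bias low-expression estimates
#' upward.
#'
#' @inheritParams g_likelihood_params
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param sampler `"gaussian"` (default) or `"rejection"`.
#' @return Numeric vector of `n` draws.
#' @export
sample_g <- function(f525, f585, ra, rg, s525, s585, n, seed,
                     sampler = c("gaussian", "rejection")) {
  sampler <- match.arg(sampler)
  p <- g_likelihood_params(f525, f585, ra, rg, s525, s585)
  if (sampler == "gaussian") {
    return(with_seed(seed, stats::rnorm(n, p$mu_g, p$sd_g)))
  }
  with_seed(seed, {
    out <- numeric(0)
    attempts <- 0
    proposed <- 0
    while (length(out) < n) {
      m <- max(2L * (n - length(out)), 1000L)
      x <- stats::runif(m, p$mu_g - 6 * p$sd_g, p$mu_g + 6 * p$sd_g)
      acc <- stats::runif(m) < exp(-(x - p$mu_g)^2 / (2 * p$sd_g^2))
      out <- c(out, x[acc])
      proposed <- proposed + m
      attempts <- attempts + 1
      if (attempts > 50 && length(out) / proposed < 1e-3) {
        stop_platemix("rejection sampler acceptance rate below 1e-3; envelope mis-specified",
                      "platemix_sampler_error")
      }
    }
    out[seq_len(n)]
  })
}

#' Empirical per-time-point fluorescence measurement error
#'
#' For every time point and both fluorescence channels, the standard
#' deviation of the `window` measurements closest in time (including the
#' point itself). A trend across the window inflates the estimate, making it
#' conservative rather than optimistic.
#'
#' @param dataset A [plate_dataset()].
#' @param well Well id.
#' @param window Number of points per estimate (default 20; shorten for
#'   short experiments).
#' @return List with positive vectors `sigma525` and `sigma585` and the
#'   `window` used.
#' @export
estimate_noise <- function(dataset, well, window = 20) {
  stopifnot(inherits(dataset, "plate_dataset"))
  if (!well %in% colnames(dataset$f525)) {
    stop_platemix(paste("unknown well:", well), "platemix_domain_error")
  }
  if (length(dataset$times) < window) {
    stop_platemix("series shorter than the noise window", "platemix_domain_error")
  }
  list(
    sigma525 = empirical_noise(dataset$times, dataset$f525[, well], window),
    sigma585 = empirical_noise(dataset$times, dataset$f585[, well], window),
    window = window
  )
}

#' Bayesian unmixing pipeline with propagated error bars
#'
#' For each tagged replicate: draw `n_ra` joint sample functions of the
#' emission-ratio curve at the replicate's ODs (posterior draws plus
#' interpolated measurement error, via [ra_at()]); pair each with one sampled
#' OD-correction curve; at every time point draw `n_g` samples of `g` from
#' the closed-form likelihood using per-time-point channel noise from
#' [estimate_noise()]; divide each `g` sample by its paired relative cell
#' density. Samples are pooled over `n_ra x n_g x` replicates per time point
#' and summarized by their mean and standard deviation — the reported value
#' and its error bar.
#'
#' Combinations where a sampled ratio falls at or below `rg` make the model
#' non-invertible and are dropped and counted; more than 10% dropped raises a
#' warning, more than 50% an error.
#'
#' @param dataset A media-corrected [plate_dataset()].
#' @param ra An [fit_ra()] result.
#' @param cal An [fit_od_calibration()] result.
#' @param constants [unmixing_constants()].
#' @param n_ra Number of emission-ratio (and OD-correction) sample curves.
#' @param n_g Number of g draws per ratio sample and time point.
#' @param seed Experiment seed; per-replicate sub-seeds are derived
#'   deterministically, so results are bit-reproducible at fixed `n_ra`,
#'   `n_g`.
#' @param noise_window Window for [estimate_noise()].
#' @return Named list of `fluor_estimate` objects per tagged replicate
#'   group; `diagnostics` holds the dropped-combination count.
#' @export
bayes_pipeline <- function(dataset, ra, cal, constants = unmixing_constants(),
                           n_ra = 50, n_g = 1000, seed = 1L,
                           noise_window = 20) {
  stopifnot(inherits(dataset, "plate_dataset"), inherits(ra, "ra_curve"),
            inherits(cal, "od_calibration"))
  groups <- tagged_groups(dataset)
  if (length(groups) == 0) {
    stop_platemix("no tagged wells in layout", "platemix_layout_error")
  }
  rg <- constants$rg
  times <- dataset$times
  n_t <- length(times)
  window <- min(noise_window, n_t)

  res <- lapply_named(groups, function(group_wells, group_name) {
    sum_pc <- sumsq_pc <- count <- numeric(n_t)
    sum_g <- sumsq_g <- numeric(n_t)
    dropped <- total <- 0
    extrap_any <- rep(FALSE, n_t)

    for (wi in seq_along(group_wells)) {
      w <- group_wells[wi]
      od_w <- dataset$od[, w]
      nz <- estimate_noise(dataset, w, window)
      # sub-seed from the well id itself, so pooled results are invariant
      # to the order wells appear in the dataset
      wseed <- derive_seed(seed, sum(utf8ToInt(w) * seq_along(utf8ToInt(w))))
      raa <- ra_at(ra, od_w, n_ra, wseed)
      extrap_any <- extrap_any | raa$extrapolated
      dens <- gp_sample(cal$gp, od_w, n_ra, derive_seed(wseed, 2L))
      dens <- pmax(dens, 1e-6)

      RA <- raa$samples                     # n_t x n_ra
      valid <- RA > rg + 1e-6
      dropped <- dropped + sum(!valid)
      total <- total + length(valid)
      MU <- (dataset$f585[, w] - RA * dataset$f525[, w]) / (rg - RA)
      SD <- sqrt(nz$sigma585^2 + RA^2 * nz$sigma525^2) / abs(rg - RA)

      # For each (time, ratio-sample) cell draw n_g standard normals; only
      # their per-cell sums and sums of squares are needed for the pooled
      # moments, so the draws are reduced on the fly.
      S1 <- S2 <- matrix(0, n_t, n_ra)
      with_seed(derive_seed(wseed, 3L), {
        for (j in seq_len(n_ra)) {
          z <- matrix(stats::rnorm(n_t * n_g), nrow = n_t)
          S1[, j] <- rowSums(z)
          S2[, j] <- rowSums(z^2)
        }
      })
      g_sum_cell <- n_g * MU + SD * S1
      g_sumsq_cell <- n_g * MU^2 + 2 * MU * SD * S1 + SD^2 * S2
      g_sum_cell[!valid] <- 0; g_sumsq_cell[!valid] <- 0
      sum_g <- sum_g + rowSums(g_sum_cell)
      sumsq_g <- sumsq_g + rowSums(g_sumsq_cell)
      sum_pc <- sum_pc + rowSums(g_sum_cell / dens)
      sumsq_pc <- sumsq_pc + rowSums(g_sumsq_cell / dens^2)
      count <- count + n_g * rowSums(valid)
    }

    frac_dropped <- dropped / total
    if (frac_dropped > 0.5) {
      stop_platemix(sprintf("%.0f%% of sampled emission ratios fell at or below rg; unmixing ill-posed",
                            100 * frac_dropped), "platemix_estimation_error")
    }
    if (frac_dropped > 0.1) {
      warning(sprintf("%.1f%% of sampled emission ratios fell at or below rg and were dropped",
                      100 * frac_dropped), call. = FALSE)
    }
    mean_pc <- sum_pc / count
    sd_pc <- sqrt(pmax((sumsq_pc - sum_pc^2 / count) / (count - 1), 0))
    mean_g <- sum_g / count
    sd_g <- sqrt(pmax((sumsq_g - sum_g^2 / count) / (count - 1), 0))
    lay <- dataset$layout[match(group_wells[1], dataset$layout$well), ]
    new_fluor_estimate(
      times = times, g_mean = mean_g, g_sd = sd_g,
      per_cell_mean = mean_pc, per_cell_sd = sd_pc,
      method = "bayes",
      flags = list(negative = mean_pc < 0, ra_extrapolated = extrap_any),
      group = group_name, strain = lay$strain, condition = lay$condition,
      n_replicates = length(group_wells),
      diagnostics = list(dropped = dropped, total = total,
                         frac_dropped = frac_dropped,
                         n_ra = n_ra, n_g = n_g, seed = seed)
    )
  })
  res
}
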