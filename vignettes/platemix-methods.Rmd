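---
title: "Quantifying fluorescence per cell from plate-reader time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fluorescence per cell from plate-reader time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platemix)
```

## The problem

Fluorescence plate readers can follow protein expression in growing
microbial cultures for tens of hours, but the measured fluorescence mixes
the reporter's signal with substantial contamination: background from the
plate and media, and autofluorescence from the cells themselves. For weakly
expressed proteins the cellular autofluorescence can dominate. The common
correction used for bacterial promoter fusions — subtract the wild-type
strain's fluorescence per OD from the tagged strain's — assumes both strains
have identical growth and identical autofluorescence per cell. In budding
yeast those assumptions fail, and the subtraction routinely produces
negative "expression".

platemix instead separates reporter signal from autofluorescence
spectrally. With one excitation wavelength (485 nm) and two emission
wavelengths, measurements of a tagged culture at each time point obey a
linear mixing model,

$$
f_{525} = g + a, \qquad
f_{585} = r_g\, g + r_a\, a,
$$

where $g$ is reporter fluorescence at 525 nm (the quantity of interest),
$a$ is cellular autofluorescence at 525 nm, $r_g$ is the reporter's
spectral constant (the ratio of its emission at 585 nm to 525 nm; for EGFP
$0.065/0.570 \simeq 0.114$), and $r_a$ is the corresponding ratio for
autofluorescence. Untagged (wild-type) wells have $g = 0$, so they measure
$r_a = f^{WT}_{585} / f^{WT}_{525}$ directly. The key modelling assumption
is weaker than the bacterial method's: tagged and wild-type cells need only
share the *ratio* $r_a$ at equal OD, not the amount of autofluorescence per
cell. Solving the model gives the direct estimate

$$
g = \frac{r_a f_{525} - f_{585}}{r_a - r_g},
$$

and dividing $g$ by the relative cell density gives mean fluorescence per
cell.

## Pipeline stages

### Media correction

Background from plate and media drifts slowly during an experiment. All
media-blank wells are pooled and each channel (OD, $f_{525}$, $f_{585}$) is
fitted over time with a Gaussian process (GP) with a squared-exponential
kernel, after centring the data (the GP prior has zero mean, so the fitted
quantity is the deviation from the channel's mean level). Measurement error
is estimated per point as the standard deviation of the 10 nearest-in-time
pooled points; if that heteroscedastic fit fails to converge, the channel
is refitted with a single constant noise learned jointly with the kernel
hyperparameters, and the object records which path was used. The posterior
mean is subtracted from every non-media well; baseline *uncertainty* is not
propagated further — it is far smaller than the other error sources the
pipeline does propagate ($r_a$ and the OD calibration).

### OD calibration

OD is a nonlinear proxy for cell density at high density. A doubling
dilution series (1x to 256x) of a saturated culture ties measured OD to
known relative density: the undiluted sample defines density 1.0. The map
OD $\to$ density is a GP with a squared-exponential plus linear kernel —
smooth, increasing, and with sane (linear) extrapolation beyond the
calibrated range; extrapolated queries are flagged. Because dilution
factors are essentially exact, the dominant error is the multiplicative OD
measurement error, so the fit's noise model is heteroscedastic with
sd $= \mathrm{cv} \times \mathrm{density}$, cv defaulting to 1% (typical
plate-reader OD repeatability). The posterior mean is verified to be
monotone on a 200-point grid; non-monotonicity is an error advising more
calibration data. Without a dilution series the package falls back to
density $=$ OD with a prominent warning. Media correction is applied
*before* the calibration map: the calibration is built from ODs of cells in
media-blanked cuvette-equivalents, so the cell-only OD is the natural input;
the ordering is stated here because either convention is conceivable.

### The autofluorescence ratio $r_a(\mathrm{OD})$

$r_a$ changes as cultures grow and media composition shifts, so it is
modelled as a smooth function of OD. Pointwise ratios
$f^{WT}_{585}/f^{WT}_{525}$ from all wild-type wells are pooled and ordered
by OD. Two estimation details matter at low OD, where autofluorescence is
weak:

* a ratio with a noisy denominator is biased upward,
  $E[f_{585}/f_{525}] \approx r_a (1 + \mathrm{cv}^2)$; each ratio carries
  a first-order (Beale-type) correction, with the denominator's noise
  estimated trend-robustly from first differences in time so that growth
  itself does not inflate it;
* the measurement error of the ratio varies strongly with OD, so it is
  estimated empirically as the standard deviation of the 20 nearest points
  along OD and supplied to the GP as fixed per-point noise.

The GP uses a neural-network covariance, whose samples have a sigmoid-like
shape matching how the ratio rises with OD, again after centring. The noise
magnitudes themselves are fitted against OD with a squared-exponential GP so
they can be interpolated to the tagged strain's ODs, which differ from the
wild-type's. Sampled $r_a$ curves used downstream are joint posterior draws
of the latent smooth function; adding the interpolated pointwise
measurement noise to each draw is available as an option but is off by
default, because a noisy draw can fall near $r_g$ where the mixing model
becomes singular, and the posterior of the smooth curve already reflects
how well the data determine $r_a$.

### Direct estimate

For each time point the wild-type ratio is averaged over replicates; the
replicate-averaged wild-type OD curve is smoothed by local quadratic
regression (tricube weights, two robustness iterations, 15% span — widened
on short series so each local fit sees at least seven points) and made
monotone by isotonic projection, giving a one-to-one OD-time correspondence
through which $r_a$ is looked up at each tagged OD. Tagged ODs beyond the
monotone wild-type range reuse the boundary value and are flagged. The
mixing model is inverted per replicate, averaged, smoothed, and divided by
calibrated density. Fast and transparent, but without error bars. Negative
estimates are reported and flagged, never clipped — clipping would bias
low-expression means upward.

### Bayesian estimate with error bars

With a uniform prior on $g$ and the autofluorescence integrated out over
the whole real line (a good approximation when the posterior of $a$ is
peaked at positive values; the package warns when the implied $a$ is within
two standard errors of zero), the per-time-point likelihood of $g$ is
proportional to a Gaussian with

$$
\mu_g = \frac{f_{585} - r_a f_{525}}{r_g - r_a}, \qquad
\sigma_g = \frac{\sqrt{\sigma_{585}^2 + r_a^2 \sigma_{525}^2}}{|r_g - r_a|}.
$$

Channel noise $\sigma_{525}, \sigma_{585}$ is estimated per time point as
the standard deviation of the 20 nearest-in-time measurements; where the
signal trends steeply across that window the estimate is inflated by the
trend, making the error bars conservative rather than optimistic. Per
replicate, 50 $r_a$ sample curves are drawn at the replicate's ODs, each
paired with one sampled OD-correction curve (drawn independently); for
every time point and $r_a$ sample, 1000 draws of $g$ are taken and divided
by the paired density. Draws can come from rejection sampling against the
unnormalized likelihood kernel under a uniform envelope over
$\mu_g \pm 6\sigma_g$ (the envelope choice is ours), or — the default —
directly from the closed-form Gaussian, which is distributionally identical
and fast; the identity is enforced by Kolmogorov-Smirnov tests. $g$ is not
truncated at zero, for the same reason negative direct estimates are kept.
Pooling the $50 \times 1000 \times$ replicates samples per time point, the
reported value is the pooled mean and the error bar the pooled standard
deviation. Sampled ratios at or below $r_g$ make the model non-invertible;
such combinations are dropped and counted (warning above 10%, error above
50%). A single experiment seed deterministically derives per-well sub-seeds
(from the well id, so results are invariant to well order), making runs
bit-reproducible.

## Gaussian-process engine

All stages share one GP implementation: zero-mean priors, fixed per-point
(or jointly learned constant) Gaussian noise, kernels squared-exponential
$\sigma^2 e^{-(x-x')^2/2\ell^2}$, linear $\sigma_b^2 x x'$, neural-network
(Williams' arcsine form — chosen because its samples are sigmoid-like; the
parameterization is our decision and is stated in the kernel
documentation), and sums thereof. Hyperparameters maximize the log marginal
likelihood, optimized in log space by bounded quasi-Newton (L-BFGS-B) from
a deterministic ladder of five starting points scaled around data-driven
initial values; the best converged restart wins, and non-convergence of all
restarts raises an error carrying the best state (this is the trigger for
the media fit's constant-noise fallback). Covariance factorizations first
try an exact Cholesky and only then add jitter, starting at $10^{-9}$ times
the mean diagonal and escalating tenfold to at most $10^{-3}$ before
declaring a numerical error. The marginal likelihood is checked in the test
suite against an independent multivariate-normal density evaluation —
the module's central oracle.

## The synthetic-data generator

Every claim is validated against a forward simulator with known truth,
emulating a yeast induction experiment: logistic growth (default rate 0.35
per hour, carrying capacity 1.2 relative-density units, 2% well-to-well
rate variation), starting densities matching starting ODs of about 0.25
(wild-type) and 0.3 (tagged); a compressive density-to-OD map
$\mathrm{od}(d) = s c \log(1 + d/c)$ with slope $s = 2.5$ and shoulder
$c = 0.37$, so nonlinearity sets in around OD 0.5 and density 1.0
corresponds to OD near 1.2; an autofluorescence emission ratio rising
sigmoidally from 0.4 to 0.6 across the OD range; reporter induction with a
2 h delay and a plateau by about 10 h; linear media drift per channel;
independent Gaussian measurement noise (OD sd 0.003, fluorescence sd 2
a.u.); sampling every 12 minutes for 20 hours; $r_g = 0.114$. The dilution
series starts from a saturated culture (density equal to the carrying
capacity), so the calibrated OD range spans the ODs reached in experiments.
Default well counts in the validation suite are 3 media, 3 wild-type and 3
tagged wells with 100 time points; these sizes keep a full Bayesian run
(50 ratio samples x 1000 draws x 3 replicates) comfortable on a laptop
while leaving the statistics sharp enough for the recovery checks below.

What the generator does *not* emulate: diauxic or otherwise multi-phase
growth, evaporation, photobleaching, well-position effects, and
non-Gaussian or autocorrelated measurement noise (a multiplicative-noise
variant exists for robustness probing only). Passing the recovery tests
therefore shows the inference is correct *under its own assumptions*, not
that those assumptions hold for any particular instrument.

## What the validation suite establishes

* the EGFP spectral constant follows from its published emission spectrum;
* the forward-model inversion and the likelihood's closed-form maximizer
  are exact to numerical precision over random parameter tuples;
* the rejection sampler is distributionally identical to the closed form
  (KS tests across seeds);
* the GP evidence agrees with direct multivariate-normal evaluation to
  $10^{-8}$;
* on the default synthetic experiment, error bars (mean $\pm$ 2 sd) cover
  the true per-cell fluorescence at $\geq 90\%$ of time points, and where
  the true signal exceeds five times the estimate's per-point noise floor
  (its reported sd) the mean is within 10% of truth — at early induction
  times the estimator's own standard error exceeds 10% of the signal, so no
  estimator without temporal smoothing could meet a pointwise 10% bound
  there, and those points are exactly the ones the gate excludes;
* with tagged autofluorescence 20% below wild-type and zero expression, the
  bacterial subtraction is negative by tens of standard errors while the
  unmixed estimate stays within $\pm 2$ sd of zero;
* OD calibration recovers relative density within 5% below the saturation
  shoulder.

## Known limitations

Time points are treated independently: the posterior of $g(t)$ has no
temporal correlation model, so error bars are pointwise, not joint. One
fluorophore per well; the algebra generalizes to the matrix case but this
implementation does not. The $r_a$ curve is only as good as wild-type OD
coverage of the tagged strain's ODs — queries outside the wild-type range
are flagged but answered by GP extrapolation. Instrument settings (gain,
bandwidths) are stored as metadata but no cross-instrument rescaling is
attempted.
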