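# platemix

Spectral unmixing of dual-emission fluorescence plate-reader time courses:
from raw OD and fluorescence readings of GFP-tagged microbial cultures to
mean fluorescence **per cell** over time, with propagated error bars.

## The problem

Plate readers make it easy to follow reporter expression in growing
cultures, but the measured fluorescence is contaminated by media/plate
background and by cellular autofluorescence, which for weakly expressed
proteins can dominate the reporter signal. Correcting by subtracting a
wild-type strain's fluorescence per OD assumes identical growth and
identical autofluorescence per cell in both strains — assumptions that fail
in budding yeast and produce negative "expression" for dim reporters.

## The method

Excite at 485 nm, measure emission at 525 nm (reporter peak) and 585 nm
(mostly autofluorescence). Each measurement is a linear mixture

```
f525 = g + a
f585 = rg * g + ra * a
```

where `g` is reporter fluorescence at 525 nm, `a` cellular
autofluorescence, `rg` the reporter's spectral constant (EGFP:
0.065/0.570 ≈ 0.114), and `ra` the autofluorescence emission ratio, shared
by tagged and untagged cells at equal OD. Untagged wells measure
`ra = f585/f525` directly; `ra` is fitted as a smooth function of OD by
Gaussian-process regression with heteroscedastic noise. Solving the mixture
gives `g = (ra*f525 − f585)/(ra − rg)`, and dividing by relative cell
density (from a dilution-series OD calibration) gives fluorescence per
cell. A Bayesian sampler propagates the uncertainty of `ra`, of the OD
calibration, and of the channel noise into per-time-point error bars.

## Worked example

Everything below runs on synthetic data with known ground truth — no
instrument files needed.

```r
library(platemix)

# a simulated 20 h induction experiment: 3 media, 3 wild-type, 3 tagged
# wells, readings every 12 minutes
sim <- generate_experiment(synthetic_scenario(), n_media = 3,
                           n_wildtype = 3, n_tagged = 3,
                           n_timepoints = 100, dt_h = 0.2)
sim$dataset
#> <plate_dataset> 9 wells x 100 time points (0.00-19.80 h)
#>   roles: media=3, tagged=3, wildtype=3

corrected <- apply_media_correction(sim$dataset, fit_media(sim$dataset))

dil <- generate_dilution_series()            # 1x..256x doubling dilutions
cal <- fit_od_calibration(dil$table$od, dil$table$dilution_factor)

ra  <- fit_ra(corrected)                     # autofluorescence ratio vs OD
est <- bayes_pipeline(corrected, ra, cal, n_ra = 50, n_g = 1000,
                      seed = 1)[["tagged_1"]]
est
#> <fluor_estimate> bayes | group tagged_1 | 100 time points
#>   per-cell fluorescence -38.4 to 603 a.u.

as.data.frame(est)[c(11, 26, 51, 76), ]
#>          strain condition time_h fl_per_cell_mean fl_per_cell_sd n_replicates method
#>  BY4741 GFP-tag synthetic      2            -21.4          340.5            3  bayes
#>  BY4741 GFP-tag synthetic      5            457.0          297.7            3  bayes
#>  BY4741 GFP-tag synthetic     10            588.3           90.1            3  bayes
#>  BY4741 GFP-tag synthetic     15            592.3           21.3            3  bayes
```

Expression switches on after 2 h and plateaus near 600 a.u. per cell (the
generator's truth is 500 a.u. on the growth scale, i.e. 600 on the
calibrated density scale). Before induction the estimate fluctuates around
zero with wide error bars — honest behaviour at low signal-to-noise, where
the bacterial subtraction method instead reports confidently negative
values. Error bars tighten as the signal grows.

For real data, put readings in a tidy CSV (`well,time_h,od,f525,f585`) and
the plate layout in a second CSV (`well,role,strain,condition,
replicate_group`, roles `media`/`wildtype`/`tagged`), then either call the
functions above via `read_plate_csv()` or use the bundled CLI:

```sh
Rscript inst/scripts/platemix analyze --data data.csv --layout layout.csv \
    --calibration dilutions.csv --method all --outdir results/
```

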