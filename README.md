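# tdmoments

Temporal moment analysis for time-domain functional near-infrared
spectroscopy (TD-fNIRS).

CW fNIRS measures only detected intensity, and most detected photons never
reached the brain — scalp hemodynamics (cardiac, respiratory, low-frequency
waves) dominate the signal. TD-fNIRS records the full distribution of
photon times of flight (DTOF) per sample; since late photons preferentially
probed deep tissue, the DTOF's temporal moments

* `M0 = -log(Σ N_i)` — optical-density analogue of the CW measurement,
* `M1 = Σ τ_i N_i / Σ N_i` — mean time of flight,
* `M2 = Σ τ_i² N_i / Σ N_i − M1²` — variance of the time of flight,

carry increasingly brain-weighted information while staying robust to the
instrument response function. A small absorption change in layer *j*
perturbs moment *n* linearly, `ΔM_n = S_nj Δμ_aj`, with sensitivities
`S_nj` computed from layered-medium photon Monte Carlo. Stacking moments
and channels, brain- and scalp-layer absorption changes separate by
covariance-weighted least squares,

    [Δμa_scalp; Δμa_brain] = (Xᵀ Z⁻¹ X)⁻¹ Xᵀ Z⁻¹ [ΔM0; ΔM1; ΔM2],

computed in the scaled, condition-safe form
`X* = ((kX)ᵀ(kZkᵀ)⁻¹kX)⁻¹(kX)ᵀ(kZkᵀ)⁻¹k` with `k = diag(1, 1e12, 1e24)`
per moment. The package's centrepiece is a general linear model posed
directly on the moments: all three moments at both wavelengths of a long
channel are fitted jointly to a short-separation-derived scalp regressor
plus sensitivity- and extinction-scaled temporal bases, solving
`β = (UᵀC⁻¹U)⁻¹UᵀC⁻¹Y` with the Kronecker-structured covariance
`C = Z ⊗ I(Nt)` never materialised. For the estimation weights, both a
theoretical shot-noise covariance (delta method under Poisson counting) and
the empirical covariance of the measured moment series are available.

The package provides, as self-contained modules:

* DTOF moment computation with both covariance models
  (`compute_moments`, `shot_noise_covariance`, `empirical_covariance`);
* a time-resolved layered photon Monte Carlo with per-layer partial
  pathlengths, exact absorption reweighting and moment-sensitivity lookup
  tables (`run_mc`, `sensitivities_from_records`, `build_lookup_table`,
  `interp_two_layer`);
* a synthetic-session generator: resting moment series with scalp-dominant
  physiology plus known injected hemodynamic responses
  (`simulate_resting`, `make_hrf`, `make_stimulus_train`, `augment`);
* seven recovery methods — CW block average (long and short channel), CW
  GLM with short-separation regression, single- and multidistance moment
  inversion, and the moment GLM (`recover_hrf`, `td_glm`);
* evaluation and benchmarking: RMSE and Fisher-z correlation to ground
  truth, paired t-tests, a full multi-subject benchmark
  (`evaluate_recovery`, `paired_compare`, `run_benchmark`).

See `vignettes/moment-analysis.Rmd` for the models, generator design and
numerical choices, and `inst/cli/tdmoments.R` for a command-line front end
(`build-table | simulate | benchmark`).

## Worked example

Build a lookup table at the two geometry separations, simulate a
five-minute resting session for four detectors, inject the canonical
response and recover it:

```r
library(tdmoments)

tab <- build_lookup_table(tissue_model(), separations = c(8, 30),
                          absorptions = seq(0.009, 0.03, by = 0.003),
                          n_photons = c(3e5, 1.5e6), seed = 101)
interp_two_layer(tab, 30, baseline_absorption(850), scalp_thickness = 13)
#> two-layer sensitivities at rho = 30 mm, mua = 0.01393 /mm, scalp 13 mm:
#>         S0 [mm]     S1 [s mm]   S2 [s^2 mm]
#> scalp 179.09995 -2.134415e-08 -7.832901e-18
#> brain  13.75977 -7.967372e-09 -5.986649e-18

geometry <- flow_geometry(4)
resting  <- simulate_resting(geometry, tab, duration = 300, seed = 7)
train    <- make_stimulus_train(300, seed = 8)
#> stimulus train: 14 onsets in 300 s (mean ISI 21 s, sd 3 s, seed 8)
session  <- augment(resting, make_hrf(scale = 1), train)

rec <- recover_hrf(session, detector = 1, method = "td_glm",
                   covariance = "ze")
#> recovered HRF (TD-GLM, covariance ze, detector 1):
#>   HbO peak 0.757 uM, HbR extreme -0.231 uM
evaluate_recovery(rec, session$truth$hrf)
#>   detector method covariance_source chromophore   rmse     r fisher_z
#> 1        1 TD-GLM                ze         HbO 0.1269 0.985     2.45
#> 2        1 TD-GLM                ze         HbR 0.0353 0.956     1.90
```

The recovered peaks sit near the injected 0.6 / −0.2 uM ground truth, and
the Fisher-transformed correlations (2.45 for HbO, i.e. r = 0.985) quantify
shape fidelity. Running all seven methods over the session's detectors and
averaging the HbO metrics reproduces the expected ranking — moment methods
beat their CW counterparts, and the moment GLM leads:

```r
suite <- run_method_suite(session)
aggregate(cbind(rmse, fisher_z) ~ method,
          data = subset(suite$records, chromophore == "HbO"), FUN = mean)
#>     method rmse fisher_z
#> 1    CW-BA 0.26    0.308
#> 2   CW-GLM 0.26    0.424
#> 3    CW-SS 0.26    0.093
#> 4   TD-GLM 0.12    1.905
#> 5    TD-LS 0.18    1.119
#> 6 TD-LS+SS 0.17    1.151
#> 7    TD-SS 0.63    0.458
```

`run_benchmark()` scales this to the full protocol (six seed groups of
twenty detectors, both covariance sources, optional amplitude sweep) and
adds paired t-tests between methods.

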