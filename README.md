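# kneebis

Personalized bioimpedance modelling of the human knee.

Transdermal delivery of anti-inflammatory drugs at the knee can be monitored
electrically: a conductive drug changes the knee's bioimpedance. But knees
differ — skin, fat, muscle and bone thicknesses and dielectric properties
vary enough between people that the same drug dose produces different
impedance changes in different subjects. `kneebis` is for researchers in
bioimpedance spectroscopy and transdermal drug-delivery measurement who need
a *subject-specific* electrical baseline of the knee: a forward model of the
tetrapolar impedance-magnitude spectrum in the 1–49 kHz band, personalized
per subject, against which drug-induced changes can later be referenced.

## What is inside

* **Cole–Cole tissue dielectrics.** Every tissue is a multi-dispersion
  Cole–Cole medium
  `eps_eff(w) = eps_inf + sum_n d_eps_n / (1 + (j w tau_n)^(1 - alpha_n)) + sigma_dc/(j w eps_0)`,
  with a packaged six-tissue reference table (dry skin, wet skin, fat, bone,
  muscle transversal and parallel to the fibers) and a diagonal-tensor
  anisotropic muscle.
* **Constrained muscle identification.** The parallel-fiber muscle
  parameters are identified from a reference permittivity/conductivity
  spectrum under the constraint of staying close to the transversal anchor
  (`identify_parallel_parameters()`): minimize the scaled parameter distance
  subject to a spectral-misfit tolerance.
* **Personalized five-layer geometry.** From sex, BMI and three knee
  circumferences: dry skin fixed at 60 um, per-sex wet-skin and bone
  constants, fat from the linear BMI relation `BMI = 0.385*SFT + 16.991`,
  muscle as the residual closing the mean radius exactly.
* **Quasi-static complex-potential FEM.** `div(sigma grad phi) = 0` with
  `sigma = j w eps_0 eps_eff` per tissue (tensor-valued in muscle), ideal
  equipotential drive/sense patches, 2D cross-sectional and extruded-3D
  tetrahedral modes, plus a mesh-free layered surrogate used for fitting.
* **Seven-parameter personalization.** `personalize()` fits wet-skin
  `d_eps3`, `d_eps4`, fat `alpha4`, `sigma_dc`, parallel-muscle `alpha3`,
  `tau4`, `sigma_dc` to a measured magnitude spectrum by Nelder–Mead in a
  log/logit-transformed space with a Levenberg–Marquardt polish, reporting
  the relative reconstruction error
  `eps_fit = ||{|Z_exp|} - {|Z_sim|}||_2 / ||{|Z_exp|}||_2`.
* **Synthetic validation cohort.** `generate_cohort()` draws virtual
  subjects with the study population's statistics (27% male, BMI 25±4,
  circumference 39±4 cm, one third osteoarthritic) and noisy 13-point
  spectra, so the whole pipeline is testable without any measured data.

## Worked example

Personalize a model for a virtual subject whose fat and muscle
conductivities differ from the reference table:

```r
library(kneebis)

profile <- subject_profile("female", bmi = 27,
                           circumferences_cm = c(41, 42.5, 40))
personalize_thicknesses(profile)
#> Five-layer knee stack (mean radius 65.519 mm)
#>   Layer 1 (dry skin)             0.060 mm
#>   Layer 2 (wet skin)             3.666 mm
#>   Layer 3 (subcutaneous fat)    28.268 mm
#>   Layer 4 (muscle)              10.765 mm
#>   Layer 5 (bone core radius)    22.760 mm

## a "measured" spectrum: the forward model at a shifted truth + 3% noise
truth <- default_parameters()
truth["Fat.sigma_dc"] <- 0.06
truth["MuscleParallel.sigma_dc"] <- 0.18
model <- knee_model(profile, apply_parameters(default_tissue_table(), truth))
measured <- add_measurement_noise(simulate_spectrum(model), 0.03, seed = 8)
head(as.data.frame(measured), 3)
#>   frequency_hz z_abs_ohm
#> 1      1000.00   6304.29
#> 2      1383.09   5249.65
#> 3      1912.93   4148.87

fit <- personalize(measured, profile)
fit
#> Personalized knee fit (surrogate forward model)
#>   eps_fit = 0.02009 (from 0.1721 at start), 1005 objective evaluations
#> Personalization parameters:
#>   WetSkin.delta_eps3       29211.6
#>   WetSkin.delta_eps4       35255.9
#>   Fat.alpha4               0.0001
#>   Fat.sigma_dc             0.065088
#>   MuscleParallel.alpha3    0.0001
#>   MuscleParallel.tau4      0.0107254
#>   MuscleParallel.sigma_dc  0.343917
```

The fit brings the reconstruction error from 17% (reference table) down to
2% — the injected noise floor. The fitted fat conductivity lands near the
truth (0.065 vs 0.06 S/m); the three parallel-muscle parameters are
reported but only weakly identified from a single noisy magnitude spectrum
(see the methods vignette on conditioning). `coef()`, `summary()`,
`predict()`, `fitted()`, `residuals()`, `plot()` and `simulate()` work on
the fitted object as on any R model; `plot(fit)` overlays measured and
fitted spectra.

A finite-element forward solve instead of the surrogate:

```r
spec <- simulate_spectrum(knee_model(profile, forward = "fem-2d"))
```

There is also a thin command line (`inst/cli/kneebis`):

```sh
kneebis cohort --n 30 --seed 1 --out cohort/
kneebis personalize --spectrum cohort/subject_001.csv \
        --sex male --bmi 24 --circumferences 39,40,38 --out fit.json
```

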