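# nfkbosc

Quantitative analysis of NF-κB (p65) nuclear translocation and its
oscillatory dynamics, for groups running image-based translocation assays
or live-cell imaging of p65-GFP reporter lines.

Activation of NF-κB is marked by translocation of the p65 (RelA) subunit
from the cytoplasm to the nucleus. Because the NF-κB target gene IκBα
re-sequesters p65 in the cytoplasm, a sustained stimulus can drive damped
oscillations of nuclear p65 in single cells — while a population-average
readout may hide them completely when cells activate asynchronously (for
instance at a low multiplicity of infection, MOI, where the first
bacterium reaches each cell at a different time). This package implements
the full computational chain needed to study that phenomenon without any
proprietary microscope software:

* **Synthetic microscopy generator** — seeded two-channel fields
  (nuclear stain + GFP) with per-cell ground-truth translocation states,
  plus noisy single-cell oscillation traces; every downstream stage is
  testable against known truth.
* **Translocation assay** — nucleus segmentation, eroded-nucleus and
  cytoplasmic-ring compartments (Euclidean-distance definitions), per-cell
  features (perimeter, circularity `4πA/P²`, compartment GFP means, GFP
  inhomogeneity), the R01–R04 gating cascade, and the per-well statistic

  `pct_nuclear = 100 · n_nuclear / (n_nuclear + n_cytoplasmic)`.

* **Delay oscillator** — a one-variable delay differential equation for
  the IκBα level *x(t)*:

  `dx/dt = −k_deg·S(t)·x − k_turn·x + k_basal + k_syn · n(x(t−τ))`,

  with the nuclear-p65 fraction given by competitive inhibition,
  `n(x) = 1 / (1 + (x/K_i)^h)`. Integrated by the method of steps with
  fixed-step 4th-order stepping and cubic Hermite interpolation of the
  delayed state.
* **Population model** — exponential first-contact activation onsets with
  hazard proportional to MOI, heterogeneous per-cell parameters, and a
  thresholded percentage-nuclear readout, reproducing the masking of
  oscillations at low MOI.
* **Trace analysis** — normalisation, prominence-based peak detection,
  first-peak alignment, and the 20-minute peak-to-peak interval histogram.

## Worked example

```r
library(nfkbosc)

## 1. synthetic plate: two wells with opposite translocation states
specs <- list(
  B2 = field_spec(n_cells = 150, fraction_nuclear = 0.85, noise_sd = 10),
  B3 = field_spec(n_cells = 150, fraction_nuclear = 0.10, noise_sd = 10))
plate <- generate_plate(specs, fields_per_well = 4, plate_seed = 20)

## 2. quantify every field and pool per well
classified <- do.call(rbind, lapply(names(plate), function(w)
  do.call(rbind, lapply(plate[[w]], function(fld) {
    feats <- quantify_field(fld$stain, fld$gfp)
    data.frame(well = w, classification = feats$classification)
  }))))
well_percentage(classified)
#>   well n_nuclear n_cytoplasmic n_excluded pct_nuclear
#> 1   B2       506            94          0   84.333333
#> 2   B3        52           548          0    8.666667

## 3. single-cell delay oscillator under a sustained stimulus
trace <- simulate_cell(oscillator_params(), stimulus_profile("sustained"))
dominant_period(trace)          # 86.8 min
detect_peaks(trace$n_p65, t_min = trace$t_min)$peak_heights
#> 0.94 0.82 0.76 0.73           # damped oscillation

## 4. MOI-dependent masking in a 500-cell population
sapply(c(100, 1), function(m) oscillation_visibility(
  simulate_population(population_config(moi = m, seed = 20))$pct_nuclear))
#> 0.75 0.00                     # visible at MOI 100, masked at MOI 1
```

The recovered well percentages (84.3%, 8.7%) match the simulated ground
truth fractions (85%, 10%) to within counting noise; the single-cell
oscillation has a period in the 80–100 min band with decreasing peak
amplitudes; and the population readout shows a clear second oscillation
peak at MOI 100 (visibility 0.75) but none at MOI 1 (0.00).

A pipeline front end is available both as `run_pipeline()` (commands
`simulate-images`, `quantify`, `simulate-cell`, `simulate-population`,
`analyze-traces`, `replay-moi-contrast`) and as a CLI script installed at
`inst/scripts/nfkbosc-cli`.

## Vignette

`vignettes/nfkb-translocation-modeling.Rmd` documents the model, the
calibration of every default parameter, what the synthetic data do and do
not emulate, and the numerical choices.
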