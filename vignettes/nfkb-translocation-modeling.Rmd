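---
title: "Methods: quantifying and modelling NF-κB nuclear translocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and modelling NF-κB nuclear translocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfkbosc)
```

# The biological problem

NF-κB dimers containing p65 (RelA) rest in the cytoplasm bound to the
inhibitor IκBα. A stimulus — a cytokine, or contact with a bacterium —
triggers IκBα degradation, p65 moves into the nucleus, and among the genes
it switches on is IκBα itself. This delayed negative feedback can produce
*damped oscillations* of nuclear p65 under a sustained stimulus, visible in
single cells by live imaging. In a population-averaged readout the same
oscillation may be invisible: when cells start at different times (for
example at low multiplicity of infection, MOI, where the first bacterial
contact is a rare event), the out-of-phase single-cell oscillations cancel.
This package provides (i) the image-analysis readout that classifies fixed
cells as nuclear- or cytoplasmic-p65, (ii) a minimal dynamical model of the
feedback loop, (iii) a population simulation connecting the two, and (iv) a
synthetic-data generator that makes the whole chain testable against known
ground truth.

# The translocation assay

Nuclei are segmented from the DNA-stain channel (Otsu threshold on a
256-bin histogram, 8-connected labelling, minimum-area filter). Two
compartments are then built per nucleus with explicit Euclidean-distance
definitions:

* **nuclear compartment** — nucleus pixels whose distance to the nearest
  background pixel exceeds `erosion_px` (default 2 px), avoiding the
  blurred nuclear boundary;
* **cytoplasmic ring** — background pixels whose distance *d* to the
  un-eroded nucleus satisfies
  `ring_distance_px < d ≤ ring_distance_px + ring_width_px`
  (defaults 1 px and 1 px), a thin annulus used as a proxy for the
  cytoplasmic GFP level. Pixels claimed by two nuclei go to the nearer
  one; exact ties go to the lower label id.

The distance-transform formulation (rather than iterated structuring
elements) was chosen because it is unambiguous and checkable against an
exhaustive per-pixel oracle — the test suite compares both compartments
*exactly* against such an oracle on hand-built 32×32 masks. Profile
presets: epithelial lines (`a549`, `ags`) use erosion 2/distance 1;
the fibroblast profile (`l929`) uses erosion 3/distance 2, reflecting its
flatter nuclei.

Per cell we record nucleus area, Crofton (4-direction) perimeter measured
on the un-eroded nucleus, circularity `4πA/P²`, mean GFP in each
compartment, their ratio, and the standard deviation of GFP over the union
of the two compartments. The union was chosen for the homogeneity readout
because the assay it reproduces gates on "standard deviation of the GFP
signal" without naming a compartment; the union is the whole measured cell
signal. Cells touching the image border (ring would be truncated) and
nuclei erased by erosion are excluded and reported with a reason.

Gating follows the translocation-assay cascade: R01 bounds on
(perimeter, circularity), R02 bounds on (mean GFP, GFP standard
deviation), then classification by an oblique boundary in the
(nuclear, cytoplasmic) intensity plane: nuclear iff
`mean_nuc > θ_nc · mean_cyt + b` (R03), else cytoplasmic (R04). The
published assay shows these regions only as screenshots, so the defaults
here are *calibrated, not transcribed*: R01/R02 default to open bounds, or
to 1st–99th percentile bands of an unstimulated control plate
(`calibrate_gates()`), mirroring the per-cell-line optimisation such
assays use in practice. `θ_nc = 1.5`, `b = 0` is scale invariant and sits
between the two synthetic state ratios (4 and 0.5). The per-well statistic
is `100 · n_nuclear / (n_nuclear + n_cytoplasmic)`; excluded cells never
enter the denominator, and a well with no classified cells reports `NA`
rather than 0.

# The delay oscillator

The model keeps a single dynamic variable, the IκBα level $x(t)$, with the
nuclear-p65 fraction slaved to it through competitive inhibition of
p65–DNA binding:

$$n(x) = \frac{1}{1 + (x/K_i)^h}, \qquad
\frac{dx}{dt} = -k_{deg}\,S(t)\,x \;-\; k_{turn}\,x \;+\; k_{basal}
\;+\; k_{syn}\, n(x(t-\tau)).$$

$S(t) \in [0,1]$ is the stimulus (sustained, pulse, or none);
transcription and translation of IκBα are collapsed into the discrete
delay $\tau$. Basal turnover `k_turn` is included so the resting state has
a finite IκBα level; the pre-stimulus steady state solves
`k_basal + k_syn·n(x*) = k_turn·x*` (unique because the two sides are
strictly monotone in opposite directions; found by bracketed root
finding, residual < 1e-10).

## Default parameters

No published rate constants exist for this reduced model, so the defaults
were calibrated **once** against the printed single-cell statistics
(damped oscillation; dominant period in the 80–100 min band; modal
peak-interval bin 80–100 min) and then frozen:

| parameter | default | units | role |
|---|---|---|---|
| `k_deg` | 0.2 | 1/min | stimulus-driven IκBα degradation (~5 min time scale when on) |
| `k_syn` | 0.6 | conc/min | maximal delayed, NF-κB-driven resynthesis |
| `k_basal_syn` | 0.03 | conc/min | basal synthesis; sets resting IκBα |
| `k_turn` | 0.01 | 1/min | basal turnover (~70 min half-life) |
| `tau` | 40 | min | transcription + translation delay |
| `K_i` | 1 | conc | inhibition constant (defines the conc unit) |
| `h` | 2 | — | Hill coefficient of the inhibition |
| `theta_nuc` | 0.5 | — | binary-call threshold, as a fraction of the dynamic range |

With these values the resting state is $x^* = 3.43$, $n^* = 0.036$ (low
background translocation); a sustained stimulus yields peaks of the
nuclear fraction at heights 0.94 > 0.82 > 0.76 > 0.73 (damped) with a
dominant period of ≈87 min. A Hill coefficient of 4 makes the relay so
sharp that damping disappears; `h = 2` is the smallest integer exponent
that yields both clear oscillation and visible damping. A short pulse
(≪ τ) produces exactly one prominent peak, and shrinking the delay to
its permitted minimum (`tau = 20·dt`) abolishes oscillation — the delay
is the oscillation's cause in this model.

## Numerics

The equation is integrated by the method of steps with fixed-step
classical 4th-order stepping (`dt ≤ tau/20` enforced). The delayed state
is read from the stored solution by **cubic Hermite interpolation** using
the stored derivative values; linear interpolation would cap global
accuracy at second order and fails a 1e-4 step-halving band at
`dt = 0.5 min`, while the Hermite scheme reaches ≈2e-6. Before a cell's
stimulus onset the solution is returned as exactly $x^*$, which also
avoids interpolating across the derivative corner at the onset. Negative
state values (possible only at extreme parameters) are clipped to zero
and counted in a warning. The test suite checks the solver against an
*independent* explicit-Euler reference: at an Euler step of `dt/100` the
two agree within 1e-3 sup-norm (at `dt/50` the first-order reference's
own error, ~2e-3, exceeds that band — a property of Euler, not of the
solver under test).

# Cell-to-cell heterogeneity and the population model

Observed peak-to-peak intervals vary between cells (printed range 40–140
min, mode 80–100 min). Heterogeneity enters through two per-cell
multipliers: on the delay, `TruncNormal(1, 0.15)` bounded to [0.5, 1.5],
and on the degradation rate, `TruncNormal(1, 0.25)` bounded to [0.3, 2].
A 60-cell ensemble then pools intervals spanning roughly 55–120 min with
modal bin 80–100 min. The spread is deliberately narrower than the
printed extremes: the printed range includes live-imaging measurement
noise on 18 manually-measured cells, while the acceptance contract
requires *all* simulated intervals to stay inside 40–140 min — the
chosen spread satisfies both statements simultaneously and was not
revisited after measurement.

Activation onsets follow a memoryless single-hit contact model (a single
attached bacterium suffices to activate a cell): per-cell first-contact
times are exponential with hazard `contact_rate_per_moi × MOI`, plus a
fixed 20-min attachment-to-translocation lag. The default hazard
(0.01 per min per MOI unit) was set so that at MOI 100 essentially all
cells activate within minutes of the lag (a fortiori within 30 min)
while at MOI 1 the mean contact time is 100 min and activation saturates
within a six-hour time course. The latter constraint matters: with a
slower hazard the MOI-1 percentage curve is still rising when the
experiment ends and its oscillation-visibility score is undefined, making
the central masking comparison unevaluable.

A cell counts as "nuclear" at a sample time when it has activated and its
nuclear fraction exceeds `n* + theta_nuc·(1 − n*)`; the population
percentage is taken over **all** cells on a 15-min sampling grid, like a
fixed-cell time course. Onsets are drawn by inverse transform from one
uniform stream per seed, so runs at different MOIs with the same seed are
coupled cell-by-cell (activation is then provably monotone in MOI).

## Oscillation visibility

The masking readout needs a scalar score. We min–max normalise the
percentage curve, detect peaks with the same topographic-prominence
filter used for single-cell traces (prominence ≥ 0.2 of the range), and
report the amplitude of the largest prominent peak *after* the dominant
one, relative to the dominant amplitude. Two deliberate choices:

* **No linear detrending.** Removing a fitted line first makes a slowly
  rising, masked curve score *higher* than a synchronized one, because
  its detrended residual range is tiny and counting noise dominates —
  the opposite of the intended meaning. Prominence filtering handles
  slow trends directly.
* The "enough points after the maximum" precondition is applied to the
  dominant *prominent* peak, not the raw argmax: on a noisy plateau the
  raw argmax is a counting-noise wiggle, often at the trace end.

With 500 cells the binomial counting noise on the percentage is ≈2
points, far below the 20-point prominence implied by the default
threshold, so the score is 0 for masked curves and ≈0.75 for
synchronized ones across seeds.

# The synthetic microscopy generator

Each field places non-overlapping cells — a disk nucleus (radius uniform
in `5 ± 1` px) plus a cytoplasmic annulus (4 px) — by rejection sampling
with a capacity error after `100 × n_cells` attempts. Each cell is
independently assigned the "nuclear" state with probability
`fraction_nuclear`; GFP levels follow the per-state nuclear:cytoplasmic
ratio (defaults 4 and 0.5) under a shared per-cell budget, the stain
channel is background plus a constant level inside nuclei, and both
channels get additive Gaussian noise clipped at zero. Geometry is in
pixels because the emulated acquisitions publish no pixel size or
magnification. Images are written 1:1 as uncompressed 16-bit grayscale
baseline TIFFs (a minimal codec included here, since the supported R
stack has no TIFF package; files are readable by standard TIFF readers).

Two deliberate strictness choices beyond the minimum contract: whole
cells (not just nuclei) are kept disjoint and away from the border, so
each ring samples only its own cytoplasm, making compartment intensities
*exactly* the configured levels in the noise-free case — this is what
lets the feature extractor be tested for equality rather than
approximation. Plates derive per-field seeds by stable hashing of
(plate seed, well, field), so any single field can be regenerated.

What the generator does **not** emulate: point-spread-function optics,
uneven illumination, photobleaching, cell motility and division, nucleus
shape irregularity, or spatial clustering of infection. A green recovery
test therefore establishes that the *analysis chain* is correct and
well-calibrated on images matching its geometric assumptions — not that
segmentation would survive pathological real-world imagery.

# Degenerate inputs and tie-breaks

* Uniform stain images yield zero nuclei via a minimum-contrast guard
  (Otsu on a flat histogram is meaningless).
* Interval histogram: half-open 20-min bins anchored at 40; the top
  regular bin is closed at 140; guard bins catch out-of-range intervals
  instead of dropping them; modal ties go to the lower bin.
* Peak detection: plateaus count once at their first point; endpoint
  maxima never count; when two peaks violate the minimum separation the
  higher (then earlier) one wins.
* Constant traces cannot be normalised (error), and traces without a
  detectable peak are excluded from alignment with a warning.
* A percentage for a well with only excluded cells is `NA`, never 0.

# Known limitations

* The model is deliberately one-variable: no IKK module, no A20, no
  transcriptional stochasticity, no paracrine feedback. It reproduces
  the damped-oscillation phenomenology, not mechanism-level kinetics.
* Gate defaults are calibrated to the synthetic intensity model; real
  data require `calibrate_gates()` on a control plate.
* The TIFF codec reads the dialect it writes (uncompressed, single
  sample, 8/16-bit, either byte order) — not compressed or tiled TIFFs.
* Live-cell tracking is out of scope; trace CSVs are taken as given.
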