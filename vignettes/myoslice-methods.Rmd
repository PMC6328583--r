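---
title: "Models and methods behind myoslice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind myoslice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoslice)
```

myoslice is a digital twin of a force-monitored myocardial slice culture
chamber together with the complete measurement chain such a device needs:
from raw magnetic-flux samples to twitch amplitudes, refractory periods,
dose-response parameters, image morphometry and transcript trends. This
vignette explains the models, their parameters and units, the numerical
choices, and what the synthetic data generators do and do not emulate.

## The instrumented chamber

A tissue slice (default 5 × 5 × 0.3 mm, `slice_geometry()`) is mounted
between a steel spring wire and a manually adjusted linear drive. Three
calibration constants define the transducer (`spring_transducer()`):

* spring constant *k* = 75 mN/mm — chosen so that ~6% shortening of a 5 mm
  span produces 22.5 mN, i.e. a systolic wall stress of
  22.5 mN / 1.5 mm² = 15 kN/m² over the slice cross-section;
* sensor sensitivity *s* = 7 T/m between tip displacement and magnetic
  flux, operating around a rest flux of at most 1.2 mT;
* a single-sample displacement resolution of 0.5 µm.

Force, displacement and flux are therefore linked by two linear maps,
`x = F/k` and `ΔB = s·x`, and `trace_to_force()` is their exact inverse.
We interpret the 0.5 µm resolution as **one standard deviation** of a
single-sample displacement estimate, because the source of that figure is
the sensor's signal-to-noise ratio; the per-sample flux noise is then
`s × 0.5 µm = 3.5 µT`. Averaging N samples improves it by √N. Flux
excursions beyond the 1.2 mT budget raise a warning but are not clipped:
the affine model is simply extrapolated, and nothing in the hardware
description suggests hard clipping. A full point-dipole field model was
considered and rejected: only the two operating-point constants are
specified, so a dipole adds parameters without adding testable behaviour.

The diastolic preload (1 mN ≈ 0.66–0.67 kN/m², the normal mean diastolic
wall stress) is established by `adjust_preload()`, which moves the drive
until the passive force matches the target within 0.01 mN.

## Tissue model

`tissue_params()` holds the ground truth that every recovery experiment
tries to re-measure through the raw-trace path.

| parameter | default | unit | meaning |
|---|---|---|---|
| `peak_twitch_force` | 6 | mN | active force at optimal length, 60 bpm |
| `time_to_peak` | 150 | ms | activation to peak force |
| `relaxation_tau` | 200 | ms | decay time constant |
| `refractory_period` | 425 | ms | baseline for stable cultures |
| `threshold_current` | 20 | mA | excitation threshold at 1 ms width |
| `restitution$floor` | 0.4 | — | relative amplitude just past the RP |
| `restitution$tau` | 300 | ms | recovery towards full amplitude |

**Twitch waveform.** A difference of exponentials,
`w(t) ∝ exp(−t/τ_d) − exp(−t/τ_r)`, normalised to unit peak. The decay
constant is `relaxation_tau`; the rise constant is solved numerically so
the peak falls at `time_to_peak`. Published recordings show the waveform
but do not parameterise it; the defaults give a twitch that is essentially
complete after ~1.2 s, comfortably inside the 5 s period of 0.2 Hz culture
pacing. The waveform is zero at activation and single-peaked by
construction.

**Length dependence.** Lengths are expressed as a fraction λ of the length
of maximal active force (L_max). The active factor is a clamped concave
parabola `max(0, 1 − ((1−λ)/0.5)²)`; the passive curve is exponential,
`P(λ) = a·(exp(β(λ − λ_slack)) − 1)` with β = 15 and λ_slack = 0.70, and
*a* calibrated at construction so that **P(0.83) = 1 mN**: the standard
preload places the tissue at 83% of L_max, the documented operating point
of the chamber. The exact functional forms are free choices; only this
calibration point and qualitative concavity/convexity are constrained.

**Force-frequency.** A piecewise-linear factor table over 12–180 bpm
(`ffr_params()`), normalised to 1 at 60 bpm. The `"cultured"` set gains
force at bradycardia — the adaptation of tissue paced at 0.2 Hz
(12 bpm) — while both sets decline from 60 to 180 bpm. The table is a
qualitative shape, not a fitted surface. Whether culture pacing at 0.2 Hz
interacts with the 60–180 bpm branch is unspecified in the source
material; the twin simply evaluates the table at the schedule's rate.

**Excitability.** A stimulus excites iff (a) its charge reaches the
threshold charge (constant-charge strength-duration: `threshold_current`
mA at 1 ms, so 10 mA at 2 ms also works) and (b) the time since the last
activation strictly exceeds the refractory period. An interval exactly
equal to the RP fails — that is what makes "the longest interval that
fails" equal the RP. A 10⁻⁶ ms epsilon keeps this boundary stable against
floating-point jitter in schedule arithmetic.

**Restitution.** Beats elicited just past the refractory period are
attenuated, recovering towards full amplitude with a 300 ms time constant
from a floor of 0.4. The floor is a twin design choice: premature beats in
paired-pulse recordings are visibly attenuated, and 0.4 keeps even the
earliest propagated beat an order of magnitude above the sensor noise, so
that the pair classifier measures the twin's refractory period rather
than a detection limit.

**Drug mechanisms** (`drug_effect()`, `apply_drug()`):

* `inotropic_scale` — force factor `1 + (E_max − 1)·C/(EC50 + C)`;
  the isoprenaline preset saturates at 5.5×.
* `rp_acute_hill` — immediate ΔRP `= E_max·C^n/(EC50^n + C^n)`;
  the dofetilide preset uses EC50 = 3 nM, E_max = 160 ms, n = 1.
* `rp_delayed` — the same Hill ceiling scaled by
  `1 − exp(−days/onset_tau)`: inert on day 0, converging to the acute
  effect. The pentamidine preset (EC50 0.2 µM, onset_tau 5 days) plateaus
  at a 312 ms increase at the standard 1 µM dose; with a 5-day onset the
  effect is >94% developed at two weeks, matching a drug that acts through
  impaired channel maturation and trafficking rather than direct block.

## Stimulation engine

Pulses are charge-balanced biphasic constant-current waveforms (default
50 mA, 1 ms charge / 1 ms gap / 1 ms discharge), with device ceilings of
75 mA and 3 ms per phase. Net charge is exactly zero for equal widths —
the property that lets electrodes run for months — and `pulse_waveform()`
samples phases at midpoints so the discrete integral is exact. The
current-to-field calibration is `E = 0.0078 V/mm/mA · I`, the midpoint of
the two published current/field anchor pairs (20 mA ≈ 0.15 V/mm,
50 mA ≈ 0.4 V/mm).

The paired-pulse protocol descends from 1000 ms to 250 ms holding each
interval for 30 s (six pairs at 0.2 Hz). The coarse decrement is 25 ms —
the source protocol states only the range and step duration, and 25 ms
gives 31 steps (~15.5 min), a plausible cadence for a scheduled protocol —
followed by an optional fine pass at 1 ms over the one-decrement window
above the coarse estimate. Multiplexing across the eight chambers of a
platform is modelled as independent schedules.

## Refractory-period analysis

`classify_pair()` decides whether the extra stimulus of a pair elicited a
second distinct contraction. The criterion is the **maximum forward rise
(drawup) of the force after the extra stimulus**: after a failed extra the
force decays monotonically, so the drawup is noise-sized, whereas any
propagated beat — however attenuated, and even riding on the decay of the
regular twitch — rises by a sizeable fraction of a twitch. The threshold
is θ = 0.10 of the reference (regular) amplitude. A simpler "second peak
above θ" rule was tried first and rejected: a premature beat close to the
refractory period can fail to produce a peak higher than the decaying
flank it sits on, biasing the RP estimate upwards by tens of
milliseconds. θ must be well below 1 (premature beats are attenuated) and
well above the noise floor; at default settings the margin on both sides
exceeds a factor of five.

`refractory_period()` takes a majority vote over the ~6 pairs of each
30 s step, then reports the longest interval whose majority failed. If
every interval succeeded the RP lies below the protocol floor
(censored low); if none did, at or above its start (censored high). The
reported precision is the decrement (or the fine step after refinement).
`measure_refractory_period()` chains coarse simulation, analysis, and the
fine pass end to end.

## Dose-response fitting

`hill_fit()` performs Levenberg-Marquardt least squares of
`R(C) = E_max·C^n/(EC50^n + C^n)` parameterised in `log(EC50)`, restarted
from eight log-spaced EC50 seeds spanning the dose range; the best
residual wins. The Hill coefficient is fixed to 1 by default — for a
single-site blocker only midpoint and ceiling are identifiable from six
doses — and can be freed. Degenerate (signal-free) data short-circuits to
`E_max ≈ 0` with an `ec50_unidentifiable` flag rather than a spurious
fit. The standard synthetic experiment uses doses
{0.3, 1, 3, 10, 30, 100} nM, six replicates, Gaussian noise of 20 ms —
chosen to mirror refractory-period assays with n = 5–6 slices and
standard errors around 18 ms.

## Morphometry

**Sarcomere length** is the inverse of the dominant spatial frequency of
the α-actinin signal within 1/3–1 µm⁻¹. The implementation projects the
image onto the fibre axis (estimated as the dominant eigenvector of the
intensity structure tensor, since striations vary fastest along the
fibre), bins the axial profile at pixel pitch, applies a Hann window,
zero-pads fourfold and refines the in-band power maximum by quadratic
interpolation of log power. Two guards precede the estimate: the dominant
frequency above 0.15 µm⁻¹ must itself lie in the band (a strong
out-of-band periodicity would otherwise leak a shoulder across the band
edge), and the peak must exceed ten times the median in-band power (pure
noise fails this). A 2% slack at the band edges keeps legitimate
periods of exactly 1 µm or 3 µm estimable. This axis-projection approach
deliberately simplifies published 2-D spectral methods to what the
measurement itself requires.

**Membrane distance** (transverse-tubule density proxy) uses an exact
Euclidean distance transform on the anisotropic voxel grid (separable
lower-envelope algorithm, implemented in C++ because no installed package
offers an anisotropic exact EDT), with a half-voxel **surface correction**
per axis: distances are measured from voxel centres to the *face* of the
nearest membrane voxel, not its centre. On a slab phantom whose membrane
surfaces are a gap *d* apart this makes the discrete mean equal the
continuous closed form *d*/4 (exactly for an even number of gap voxels),
instead of overestimating it by one voxel in ten at *d* = 1 µm.

**ECM fraction** is the volume fraction of segmented membrane/ECM signal;
segmentation is Otsu's threshold by default (the source method states
only "threshold-based"). **Cross-section areas** label the connected
intracellular regions of a transverse plane, discard components touching
the border (cells cut by the field of view) and components under
50 µm² (capillary lumina — a plausible myocyte-scale cut-off, not a
published value), and flag oversized components that indicate broken
membranes merging neighbouring cells.

The phantom generators (`gen_striated_stack()`, `gen_slab_stack()`,
`gen_cell_grid_stack()`, `gen_labelled_stack()`) are first-class,
seed-reproducible code. They emulate periodicity, orientation, intensity
noise, smooth phase disorder and simple geometry — not point-spread
blurring, depth attenuation, chromatic shift or biological heterogeneity.
Passing tests on phantoms therefore validates the estimators' numerics
and calibration handling, not their robustness to every confocal
artefact.

## Transcript trends

Log2 ratios of cultured versus fresh tissue from the same patient are
regressed on culture day by ordinary least squares over the culture days
only (8, 14, 24, 35) — no synthetic day-0 point is added; this convention
reproduces the published intercept and slope×35 columns of both reference
tables within the ±0.02 allowed by their two-decimal rounding. The
intercept is the day-0 extrapolation (immediate culture adaptation);
slope×35 is the drift over the full window, one unit per doubling.
`log2_ratio()` adds a 0.5 pseudocount only when a count is zero. Trend
classification uses |slope×35| ≥ 1, i.e. at least one doubling over five
weeks — a documented, deliberately simple cut-off. The regression pools
the contributing patients (days 14 and 35 derive from the same patient);
no patient-effect adjustment is attempted because the published summaries
are plain per-gene OLS.

## Simulation mechanics and numerical choices

`simulate_run()` establishes the preload, passes every schedule event
through the excitability gate sequentially (activations update the
refractory clock, so a captured extra stimulus delays nothing for the
next regular beat 4 s later), and superposes twitch waveforms
additively on the diastolic force. Peak amplitudes carry the
length-tension factor at the operating length, the force-frequency factor
at the schedule rate, the restitution factor, and (optionally) a slow
medium-exchange modulation. The force is converted to flux and calibrated
Gaussian noise is added from a private RNG stream, so simulations are
bit-reproducible for a seed and never disturb the caller's RNG. The
feedback of intra-twitch shortening on active force (~6% of span) is
neglected; diastolic force therefore equals the preload exactly in
noise-free runs, which is also the twin's documented invariant.

Default problem sizes keep every experiment desk-scale: traces are 500
samples/s, a full coarse-plus-fine refractory protocol simulates ~28 min
of chamber time (~840k samples) in a few seconds of compute, and the
morphometry phantoms are 256² pixels. These sizes are the package's
standard experiment definitions and are what the test suite and the
acceptance script run.

## Known limitations

* No ionic/action-potential model: the refractory period is a scalar
  state, which is exactly what the paired-pulse assay observes.
* No oxygen/nutrient transport, no multi-day electromechanical
  remodelling coupled to the transcript module.
* The affine sensor ignores the 3-D geometry of the real magnetic field;
  axial versus transverse magnet motion is not distinguished.
* The medium-exchange modulation is a sawtooth amplitude envelope, a
  caricature of the real post-exchange recovery kinetics.
* Arrhythmia phenomena (delayed contractions, tachycardia) are outside
  the twitch detector's scope beyond generic extra peaks.

```{r example}
tissue <- tissue_params()
sched <- pacing_schedule(0.2, 60)
trace <- simulate_run(tissue, sched, run_config(duration = 60, seed = 1))
ev <- detect_twitches(trace, sched)
nrow(ev)
round(mean(ev$amplitude), 2)
```
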