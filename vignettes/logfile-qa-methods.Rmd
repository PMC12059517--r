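---
title: "Log file-based QA for PBS proton therapy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Log file-based QA for PBS proton therapy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lfqa)
```

## The problem

A pencil-beam-scanning (PBS) proton gantry delivers a plan spot by spot:
within each energy layer the beam is steered across a scan grid, dwelling on
each position until the planned monitor units (MU) are accumulated. The
nozzle's strip-segmented ionization chambers measure every spot's lateral
position (by fitting a Gaussian to the per-strip charge profile) and its
accumulated charge; the machine writes these to *record* log files, and a
separate *events* stream carries status and interlock messages. Log
file-based QA (LFQA) uses these records, instead of phantom measurements,
to verify each delivered fraction: per-spot accuracy and reproducibility,
the dosimetric impact of the observed deviations, and the stability of the
delivery time structure.

`lfqa` implements this analysis chain together with a synthetic delivery
simulator, so that the whole pipeline can be developed and validated
without access to clinical log files (which are generally not shareable).

## From chamber readings to spot parameters

Three small operations connect the machine-level record to the plan-level
quantities; all three are exercised by the log reader:

* **Strip centroid**: `fit_strip_centroid()` fits a three-parameter
  Gaussian (amplitude, center, width) to the strip charges by least squares
  (`minpack.lm::nlsLM`), initialized from the charge-weighted mean and SD.
  A peak on a boundary strip is a coverage error. The synthetic profile
  generator distributes the spot charge over strips as exact Gaussian mass
  per pitch interval, so the fit's round-trip accuracy (< 1e-6 mm
  noiseless) is tested against ground truth.
* **Isocenter projection**: chamber-plane positions are scaled by the
  intercept theorem, `x_iso = x_ic * sad / (sad - z_ic)`, with separate
  virtual source-axis distances per scanning axis. The projection is linear;
  geometry values are configuration, not constants.
* **MU conversion**: `MU = charge × k × (p_ref / p) × (T / T_ref)` — the
  machine calibration factor with the conventional air-density correction
  for the ambient conditions in the record header.

The record dialect is a per-field CSV (header lines prefixed `#`) carrying
per-spot averaged chamber-plane positions; raw 4 kHz samples are out of
scope. Events are JSON-lines. Spot matching to the plan is by
`(field, layer, spot)` index — deliveries preserve plan order — and a
fraction with fewer logged than planned spots is flagged aborted and
excluded from course-level statistics, pass rates and timing.

## Per-spot statistics

For logged values $L_{i,s}$ over fractions $i = 1 \dots N$ and planned value
$P_s$:

$$\mu_s = \frac{1}{N}\sum_i (L_{i,s} - P_s), \qquad
  \sigma_s = \sqrt{\frac{1}{N-1}\sum_i (L_{i,s} - \bar L_s)^2}$$

computed for x, y and MU, plus the mean 2D distance
$\overline{d_s} = \tfrac1N \sum_i \sqrt{\Delta x_{i,s}^2 + \Delta y_{i,s}^2}$.
The distance averages the per-fraction distances rather than taking the norm
of the mean deviation; both are reported (`mean_distance`,
`distance_of_means`) since the two differ whenever deviations fluctuate
(Jensen: `mean_distance >= distance_of_means`). The method is designed for
courses of at least 15 fractions; fewer are accepted with a warning.
Aggregation (per plan or per gantry angle) reports the mean, the *worst*
value — largest magnitude with sign preserved, so a table cell can read
`0.0 (-1.4)` — and a five-number summary with quartiles by the
linear-interpolation convention (`quantile` type 7) and whiskers at the
furthest point within 1.5 IQR, which is what the violin summaries use.

## Pass rates

The spot-based pass rate of fraction $i$ is the MU-weighted share of spots
delivered within a tolerance distance $D$:

$$\Lambda_i(D) = \frac{\sum_s \mathrm{MU}_{i,s}\,[d_{i,s} < D]}
                     {\sum_s \mathrm{MU}_{i,s}} \times 100\%$$

Numerical choices: the inequality is strict (ties at $d = D$ fail), the
weights and the denominator are the fraction's *logged* MU, and the default
tolerance is 1 mm, paired with the 1%/1 mm gamma criterion. $\Lambda$ is
invariant under uniform MU rescaling and monotone in $D$; $\Lambda(0) = 0$
for continuous noise.

The reference position is either the planned position or, in the
first-fraction mode, the first delivered fraction's logged position
spot-by-spot — emulating comparison against a clinically approved
pre-treatment QA delivery. In that mode fraction 1 scores 100% on both
metrics by construction, and the gamma normalization follows the
first-fraction reference dose maximum. The open choice of which MU enters
the denominator in that mode is resolved to the *per-fraction* logged MU.

Pearson correlation between the $\Lambda$ and $\Gamma$ series uses the
sample product-moment coefficient (`stats::cor`); a zero-variance series
makes it undefined and it is reported as missing (`NA`), never as 0.

## Dose reconstruction

The engine replaces a treatment planning system: analytic pencil-beam
kernels superposed on a homogeneous water grid (default 3 mm isotropic
voxels). Per spot, the dose is MU × a normalized depth-dose × a normalized
2D transverse Gaussian centered on the spot's (x, y) with
$\sigma(z) = \sigma_0 + k z$. The depth-dose has a quadratic build-up
plateau and a Gaussian Bragg peak at the range $R(E) = \alpha E^p$ (defaults
$\alpha = 0.022$ mm/MeV$^p$, $p = 1.77$, reproducing the familiar ~76 mm
range at 100 MeV); it is normalized to unit area so integral dose equals
total in-grid MU, which the tests bound to < 1% leakage on the default
geometry. The field axis is the beam direction rotated by the gantry angle
about the room-frame y axis; spot axes are parallel (divergence is handled
upstream by the isocenter projection); couch angles and heterogeneity are
unsupported. The lateral kernel is truncated at 4σ (mass error 3×10⁻⁴).

Physical fidelity is explicitly *not* the goal: the engine exists so that
position and MU perturbations propagate to dose with realistic, smooth
sensitivity. It is deterministic and linear in MU, which the suite checks
bit-exactly.

## 3D gamma analysis

For each reference voxel at or above the low-dose cutoff (default 10% of
the normalization),

$$\gamma(r) = \min_e \sqrt{\frac{|r-e|^2}{\mathrm{DTA}^2} +
  \frac{(D_e - D_r)^2}{(\Delta D)^2}}, \qquad
  \Delta D = \frac{\mathrm{dose\%}}{100} \cdot D_{\mathrm{norm}}$$

with the evaluation dose sampled by trilinear interpolation on a lattice of
step 10% of the DTA within a search radius of 3×DTA (configurable). The
normalization is fixed once per series from the reference dose maximum.
Numerical choices: the pass condition is inclusive (γ ≤ 1); the cutoff
applies to reference voxels only; offsets are visited in order of
increasing distance so the early exit — stop once the distance term alone
reaches the current best γ² — is *exact*, not approximate, and the tests
compare the optimized path per voxel against an exhaustive dense-search
oracle written independently in R. Beyond the search radius the
distance-capped γ is recorded as-is. Voxels whose whole search lattice
falls outside the evaluation grid score γ = ∞ and raise a boundary
warning.

## The delivery simulator

`simulate_fraction()` is the package's stand-in for a treatment machine,
emulating the error phenomenology seen in clinical log files:

* a gantry-angle-dependent systematic x offset, default profile
  $-A\sin\theta$ — negative at 90°, positive at 270°, zero for vertical
  beams — pluggable as a function;
* reproducible per-scan-row y offsets (drawn once per row from
  $U(-1,1) \cdot$ `y_row_offset`, constant across fractions), emulating
  scanning-magnet calibration imperfections;
* a per-(layer, fraction) random y shift for degraded layer tuning;
* per-spot per-fraction Gaussian position noise (defaults sized at
  0.1–0.2 mm), inflated for high-MU spots on the lateral field edge —
  defined as spots within one scan pitch of the layer's 2D convex hull,
  since no formal definition exists;
* MU bias and noise, with delivered MU clipped at 0 but *not* re-floored at
  the 0.014 MU planning minimum (a delivered spot may record slightly below
  it);
* timing: drill time proportional to MU, Gaussian spot-switch and
  energy-switch intervals, and optional interlocks inserted as paired
  events inside a gap. All timestamps are integer microseconds, so timing
  conservation (drill + spot switch + energy switch + interlock = field
  span) holds exactly, and derived times are reported in seconds.

Randomness is drawn from substreams keyed by
`(seed, fraction, field, layer)` — an LCG-style integer mix — so identical
seeds give bit-identical logs and adding fractions never perturbs earlier
ones. Row offsets use fraction-index 0 streams, which is what makes them
systematic. Where the underlying magnitudes are not publicly quantified
(layer-tuning shift, interlock frequency and duration), the defaults are
free parameters chosen once at plausible machine scales (0.1 mm tuning
shifts, ~7% of fields interrupted, ~30 s interruptions) and documented at
the `error_model()` interface.

What the simulator does *not* emulate: patient anatomy and setup error,
beam-optics physics behind the angle dependence (only its signature),
intra-spot 4 kHz structure, double-scattering deliveries, and correlated
drifts across days. Passing tests therefore demonstrate that the analysis
chain measures what it claims on data with known ground truth — not that
any particular clinic's machine behaves like the defaults.

## Timing decomposition

Per field, drill time is the sum of per-spot `t_end - t_start`; gaps
between consecutive spots are spot switching within a layer and energy
switching across a layer boundary (layer boundaries come from
`layer_index` changes in the record). Any portion of a drill or gap covered
by an interlock interval is re-attributed to interlock time, so excision is
category-neutral and delivery time (drill + switches) excludes
interruptions; beam-off time between fields is never counted. Summaries
report mean and 2σ (double corrected sample SD) of delivery time per field
and per plan, and the percentage of interlock-free field deliveries.

## Problem sizes and design choices in the test suite

The suite validates at desk scale, chosen so the full run stays fast while
estimates are statistically tight: formula oracles on 1000 randomized
instances (tolerance 1e-12); gamma oracle equivalence on 10³-voxel grid
pairs with a 1.5×DTA search radius (the dense R oracle is exhaustive, so
equivalence is exact, not sampled); parameter recovery on 1000 spots × 30
fractions (mean μ within ±0.02 mm, mean σ within 10%, acknowledging the
c₄ bias of the sample SD, ~1% at N = 30); dose/gamma properties on 40³ ×
3 mm grids with ~2000-spot two-field plans; and timing conservation in
exact integer microseconds. The pipeline demo runs 2 fields × 2–3 layers ×
20–50 spots over 4–15 fractions. `scripts/acceptance.R` reports the
pipeline's headline quantities for a 1200-spot, 15-fraction course under
the default error model, including day-to-day switch-time jitter (0.2 ms
spot switch, 0.15 s energy switch) so timing reproducibility is a
non-trivial ~0.7 s (2σ).

## Known limitations

* The dose engine is a sensitivity model, not a dose calculation: no
  heterogeneity, nuclear halo, range straggling detail or absolute
  dosimetry.
* Single averaged chamber plane per axis; per-chamber redundancy checks are
  out of scope.
* Gamma is global only — no local-dose mode, masks or ROIs.
* One interlock at most per simulated field delivery; clinical deliveries
  can have several.
* The Λ–Γ correlation depends on how much day-to-day variability the error
  model injects; with purely independent small noise both series sit near
  100% and the correlation estimate over 15 fractions is weak or undefined.
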