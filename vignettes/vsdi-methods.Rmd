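---
title: "Models and methods behind the vsdi pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the vsdi pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsdi)
```

# Scope

`vsdi` implements the standard analysis chain for trial-based widefield
voltage-sensitive dye imaging (VSDI) of rodent barrel cortex — ΔF/F
preprocessing with blank-trial artifact subtraction, barrel-ROI mapping,
temporal response metrics, concentric-ring spatial-spread profiling,
seed-pixel synchrony analysis with spatial-shuffle nulls, and nonparametric
group comparisons — together with a movie simulator that reproduces the
statistical structure such recordings are assumed to have. This vignette
documents the models, the tunable parameters and their defaults, the
numerical choices, and what the simulator does and does not establish.

# The synthetic movie model

The simulator is the package's validation backbone: every analysis stage is
tested against movies whose ground truth is known exactly. Raw fluorescence
is generated multiplicatively,

$$F(t,x,y) = F_0(x,y)\,\bigl[1 + R(t,x,y) + S(t,x,y) + H(t)\bigr]\,B(t) + \varepsilon(t,x,y),$$

with resting fluorescence $F_0$ (flat at 1000 counts; halved on blood-vessel
pixels), an evoked response $R$, spontaneous activity $S$, a heart-beat
oscillation $H$, photobleaching $B$, and white measurement noise
$\varepsilon$ with sd `noise_sd`·$F_0$. The multiplicative form is chosen so
that ΔF/F preprocessing ($F/F_0^{\text{baseline}} - 1$) recovers
$R + S + H$ exactly in the noise-free limit, which turns parameter-recovery
tests into algebraic identities rather than approximations.

## Evoked response

At a pixel a distance $d$ (µm) from the activated barrel's center, the local
time is

$$\tau = t - \max(0,\, d - \sigma_0)/v,$$

i.e. the initial thalamocortical footprint of width $\sigma_0$
(`spread_sigma0`) depolarizes synchronously and a wave propagates outward
from its edge at speed $v$ (`propagation_speed`). For $\tau > 0$,

$$R = A \cdot \frac{g(\tau)}{g(t^{*})} \cdot
      \exp\!\left(-\frac{d^2}{2\,\sigma(\tau)^2}\right),
  \qquad g(\tau) = e^{-\tau/\tau_d} - e^{-\tau/\tau_r},$$

with $\sigma(\tau) = \sigma_0 + \gamma\tau$ (`spread_growth` $\gamma$) and
$t^{*} = \ln(\tau_d/\tau_r)\,\tau_r\tau_d/(\tau_d-\tau_r)$ the analytic
argmax of $g$ (`evoked_peak_time()`), so the center-pixel peak equals the
injected amplitude $A$ exactly. The synchronous core is a deliberate design
choice: with a pure radial delay $d/v$, pixels two or three pixels from the
center are still on the steep rising phase at the 20 ms reference frame and
the early activated area collapses to a few pixels, far below the
barrel-sized region (~15–20 px at 50 µm/px) that the 75–80 % threshold
convention is known to produce. With the core, the noise-free default barrel
thresholds to 21 px while ring latencies still increase strictly with
distance.

## Spontaneous activity, heart beat, bleaching

$S$ is spatiotemporal white noise convolved with an isotropic Gaussian of sd
`spont_corr_length` and passed through a first-order autoregression with a
fixed 100 ms time constant, then scaled so its per-pixel sd is
`spont_amplitude` *everywhere* — the normalization uses the exact per-pixel
kernel norm, so the contract holds at grid edges and when the correlation
length is comparable to the grid (where an interior-only normalization
silently deflates the field).

$H$ is a spatially uniform sinusoid at `heartbeat_freq` (9 Hz). Its phase is
**fixed across trials by default** (`heartbeat_phase = 0`), emulating
ECG-triggered frame acquisition. This is what makes the artifact removable:
the averaged blank carries the same $H\cdot B$ trend as every evoked trial,
so blank subtraction cancels it to first order, and residualization (mean
across trials removed) cancels it exactly. With a random phase per trial
neither operation could remove it — a per-trial phase argument is available
for simulating unlocked rigs, but it is not the default. $B$ is a single
exponential with time constant `bleach_tau` shared by all pixels
(`Inf` disables it).

Blood vessels are curvilinear random walks (1–2 px wide, entering from a
random border, heading diffusion 0.3 rad/step, capped at a 15 % masked
fraction); the walk rules are documented in `generate_vessel_mask()` so the
procedure can be replayed step by step as an independent test oracle.

## Default parameters

The two presets are calibrated to the grand-average scale reported for this
preparation, not fitted to any dataset:

| parameter | Ctrl | Tg | meaning |
|---|---|---|---|
| `evoked_amplitude` | 4.3e-3 | 7.3e-3 | peak ΔF/F at the barrel center (Tg ≈ 1.7×) |
| `spread_sigma0` (µm) | 120 | 120 | initial footprint width |
| `spread_growth` (µm/ms) | 2 | 6 | spatial widening rate |
| `propagation_speed` (µm/ms) | 15 | 15 | horizontal wave speed (0.015 m/s, slow end of the reported subthreshold range) |
| `rise_tau` / `decay_tau` (ms) | 25 / 120 | 35 / 120 | waveform time constants → time-to-peak ≈ 50 / 60 ms on the 10 ms grid |
| `spont_corr_length` (µm) | 200 | 100 | spatial correlation length of resting activity |
| `spont_amplitude` | 1e-3 | 1e-3 | per-pixel sd of S (ΔF/F units) |
| `noise_sd` | 1e-3 | 1e-3 | per-frame shot noise / $F_0$ |
| `heartbeat_amp`, `heartbeat_freq` | 5e-3, 9 Hz | same | ECG-locked oscillation |
| `bleach_tau` (ms) | 20000 | same | ≈ 2 % fluorescence loss over a 400 ms trial |

The propagation speed is deliberately slow so that successive 200 µm rings
peak more than one 10 ms frame apart, keeping the latency-ordering property
testable at frame resolution. Per-animal heterogeneity in `generate_cohort()`
is multiplicative log-normal jitter (default sd 0.10) on the response-shape
and spontaneous-structure parameters.

# Preprocessing decisions

* **ΔF/F is $F/F_0 - 1$** with $F_0$ the per-pixel mean of the 3 frames
  (30 ms at 100 Hz) before stimulus onset, or the first 3 frames of
  unstimulated trials. Division (rather than a fixed offset) makes the
  result invariant to per-pixel gain, and blank subtraction then cancels
  multiplicative artifacts to first order.
* **Pipeline order is fixed**: ΔF/F → blank subtraction → vessel exclusion →
  analysis. Vessel pixels become `NA` at the ΔF/F stage and stay missing
  through every downstream mean ("missingness is monotone").
  `smooth_for_display()` (σ = 1.5 px, missing-aware) is terminal-only;
  nothing quantitative consumes its output.
* **Vessel detection** thresholds the σ = 2 px high-pass residual of the
  blank frame average at `threshold_k` robust standard deviations
  (MAD × 1.4826, default k = 3). The high-pass width is the field's
  convention; the MAD rule is this package's documented choice for the
  unspecified threshold, selected for robustness to the heavy-tailed
  residual distribution the vessels themselves create.

# ROI and rings

The barrel center is the argmax of the trial-averaged 20 ms frame (ties →
smallest row, then column). The ROI is the 8-connected component containing
the center among pixels at or above `threshold_fraction` (default 0.775, the
midpoint of the conventional 75–80 % band) of the center value. The
connectivity restriction is an addition: pure thresholding lets isolated
noise pixels join the ROI. A fractional threshold is exactly invariant under
positive rescaling of the frame; under general strictly increasing transforms
only the center is guaranteed invariant.

Rings are half-open Euclidean annuli between pixel centers,
$(i-1)w < d \le iw$ with $w$ = 200 µm (4 px), the center pixel itself in no
ring; ring 1 of an interior center therefore holds exactly 48 lattice pixels.
Rings clipped by the grid border are allowed, with clipped and masked counts
reported and a warning above 20 % loss. Spatial profiles are referenced to
the inner-ring value 20 ms after onset; default sample times are 20, 50 and
80 ms (configurable — 40 ms is an equally common middle choice).

# Synchrony analysis

Correlations are zero-lag Pearson *r* between residual traces (single trials
minus the across-trial mean, so the stimulus-locked component and every
trial-invariant artifact vanish) in a sliding window of ± 4 frames — nine
frames ≈ 80 ms at 100 Hz, honoring the "± 40 ms" reading; an 8-frame window
is available via the argument. Per-window *r* values are combined by plain
averaging over window positions, trials, and seed pixels (not Fisher-z; the
plain mean matches how such values are conventionally reported, and a z
transform would only matter at |r| near 1). Zero-variance windows are
missing, never zero; the map cell at the seed itself (r = 1 by definition)
is always excluded. Analysis windows default to 2500 ms for spontaneous and
150 ms post-stimulus for evoked data.

Neighborhood synchrony is the mean over the 48 cells within 200 µm
(`floor(radius/pixel_size)` = 4 px) of the seed. `aligned_synchrony_map()`
averages seed-centered 51 × 51 px maps (± 1.25 mm);
`roi_neighborhood_synchrony()` computes the same per-seed statistic without
building display-size maps, which makes the 100-iteration shuffle null
affordable; `shuffle_null()` uses that route so observed and null values are
exactly comparable. The spatial shuffle draws a fresh permutation of
non-vessel pixel positions for every frame of every trial — the stricter
reading of per-frame shuffling — and recomputes the full statistic per
iterate. Restricting the permutation to non-vessel positions preserves the
missing-data pattern.

Two finite-size behaviors are worth knowing. First, within-window centering
removes the slow shared component of the signal inside each 80 ms window, so
the measured *r* between genuinely correlated pixels is substantially
attenuated relative to the field's instantaneous spatial correlation; with
the default parameters the spontaneous neighborhood synchrony of the
control-like preset comes out near 0.15, which is the scale reported for
this preparation. Second, the spatial mean of each frame is invariant under
any within-frame permutation, so on small grids the shuffle null is not
exactly centered on zero — the common-mode variance fraction scales roughly
with (correlation length / grid size)². At the full 100 × 100 px geometry
the effect is negligible; the test suite checks the ± 0.02 centering
criterion on fields of ≥ 900 pixels.

# Group statistics

Per-animal values (never per-trial) are the units of inference. Group
comparisons use the two-sided Wilcoxon rank-sum test, exact for combined
n ≤ 20 without ties, otherwise the normal approximation with tie and
continuity correction; the choice is recorded in the result. Observed
synchrony is compared with its shuffle-null mean per animal by the two-sided
Wilcoxon signed-rank test (exact for ≤ 25 nonzero differences without ties;
zero differences dropped and counted). α = 0.05, results reported as
mean ± SEM; no multiple-testing correction is applied, and reports should
say so. Both tests are delegated to `stats::wilcox.test`; the test suite
verifies the exact branches against exhaustive enumeration of all group
assignments (rank-sum) and sign assignments (signed-rank) for group sizes up
to 8, and checks the realized type-I error of the 8-vs-6 design over 2000
null simulations.

# What a green test establishes — and what it does not

The simulator reproduces the *statistical structure* the pipeline assumes:
localized-then-spreading evoked responses, spatially correlated spontaneous
activity with genotype-dependent correlation length, ECG-locked heart beat,
shared bleaching, vessel dropout, shot noise, and between-animal parameter
jitter. It deliberately omits dye bleaching nonlinearity and wash-out,
cortical lamination, hemodynamic contamination, motion, anisotropic or
plaque-shaped spread, and any biophysics of dye–membrane interaction.
Parameter-recovery tests therefore validate the *analysis* (the estimators
recover what was injected, at the injected effect sizes), not the biology of
any particular dataset.

Known limitations:

* Under default noise at 20 trials, pixels sitting near the 77.5 % threshold
  drop out of the connected component, so measured ROIs (~8–9 px) are
  smaller than the noise-free 21 px design size; real averaged maps, whose
  neighboring pixels share signal more strongly, sit closer to the 15–20 px
  convention.
* The response model's amplitude is Gaussian in distance at every instant,
  so a spatial profile that *increases* with distance at a fixed pre-peak
  time (as extreme network hyperexcitability can produce) is outside the
  model class; the transgenic-like preset instead produces the achievable
  form of that dissociation — a much flatter fall-off that dominates the
  control profile at every ring at 80 ms.
* Ring latency spacing is tuned to exceed one frame for testability; real
  preparations can show sub-frame spacing, where per-animal latency
  differences only emerge in across-animal averages.
* `run_pipeline()` holds one animal's movies in memory at a time (~350 MB at
  full scale); `generate_cohort()` materializes the whole cohort and is
  intended for reduced geometries.

# Numerical choices

* Sliding-window correlations use cumulative sums (O(frames × pixels) per
  seed and trial); windows whose variance is ≤ 1e-12 of their mean-square
  are treated as degenerate (missing), and *r* is clamped to [−1, 1] against
  rounding.
* Gaussian kernels are truncated at 3 sd (radius ≥ 1 px); border pixels
  renormalize the kernel over in-grid support so constants are preserved,
  and the missing-aware variant renormalizes over non-missing support.
* Time-to-half-peak interpolates linearly between the bracketing frames; on
  a 10 ms grid the interpolation error against the closed-form decay is
  well under 1 ms.
* Peak ties resolve to the earliest frame; argmax ties in maps resolve to
  the smallest row, then column.
* All randomness flows through integer seeds (`with_seed` semantics: the
  caller's RNG state is never disturbed); every generator output is a pure
  function of (geometry, parameters, seed), and sub-seeds are drawn below
  2^31.
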