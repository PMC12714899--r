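---
title: "Methods: quantifying thermal gradient test behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying thermal gradient test behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgtkit)
```

## The assay and its coordinate conventions

In the thermal gradient test an animal roams a corridor whose floor spans a
linear temperature gradient; its tracked center-of-mass position over a
10-minute (or longer) recording is the raw datum. `tgtkit` fixes the
coordinate origin at the **cold end** (`x = 0`), so the calibration
intercept is the cold-end temperature and zones are numbered 1..14 from
cold to hot. Zone bins are half-open `[lo, hi)` with the last zone closed
at the corridor end — the standard histogram convention, which makes the
zone partition cover the arena exactly once. Time windows are likewise
half-open `[start, end)`.

The default calibration is the nominal endpoint line (4 °C at 0 cm, 58 °C
at 137 cm, slope 54/137 ≈ 0.394 °C/cm). A calibration fitted from
thermocouple measurements (`fit_calibration()`) replaces it when
measurement points are available; fits are labeled `nominal` or `fitted`
so reports always state which map produced the temperatures. Note that a
measured mid-corridor fit need not pass exactly through the endpoint
temperatures; both modes are therefore supported rather than reconciled.
For a zero-variance calibration response, R² is defined as 0 (not NaN) so
reports never contain undefined fields.

## Preprocessing

The first 30 s of a recording are excluded by default
(`preprocess_spec()`): immediately after placement mid-gradient the animal
explores, and those frames would dilute the stationary preference signal. A
10-min recording at 15 frames/s thus yields 8,550 analyzed frames. After
exclusion, timestamps are re-zeroed so all windows are expressed relative
to analysis start. Irregular timestamps are resampled to the nominal frame
grid by nearest-sample interpolation, and tracking gaps longer than 1 s are
flagged in the track's metadata rather than silently interpolated.

Median smoothing of positions (window 5 frames) is **off** for occupancy —
zone binning is robust to sub-cm tracking jitter — but **on** by default
for distance and speed, where jitter accumulates into spurious path length.
This split is a package decision; fixed-rate trackers give no guidance
either way.

## The Gaussian preference model and its fit

Occupancy at zone-center temperature `T` is modeled as
`A · exp(−(T − T_peak)²/(2·SD²))`. Two amplitude conventions coexist:

* `normalized_2p` — predictions are normalized to sum to 100 % over the
  zones; peak occupancy is then a deterministic function of SD. This is the
  conceptual readout ("a narrower distribution has a taller peak").
* `free_3p` — the amplitude is a third free parameter. This is the
  **default for fitting and for nested comparisons**: with pooled
  per-animal × per-zone points (12 animals × 14 zones = 168 points, 165
  residual df), single-numerator-df F tests require three free parameters
  per curve, and the free amplitude also absorbs the mild flattening that
  boundary reflection and resting impose on real profiles.

Fits are performed on the **pooled points**, not on the group-mean curve:
the mean curve would hide the animal-to-animal scatter that the F test's
denominator df must represent. No per-zone weighting is applied (none is
standardly defined for this assay).

Numerically, the sum of squares is minimized by a coarse grid over the box
`T_peak ∈ [4, 58] °C × SD ∈ [0.5, 40] °C` at 0.5 °C steps, followed by
box-constrained L-BFGS-B refinement (relative SS tolerance ~1e-12 via
`factr = 1e4`). In `free_3p` mode the amplitude is profiled out in closed
form at every evaluation (variable projection), so the search is always
two-dimensional. The grid-then-refine scheme avoids the multimodality traps
of pure descent on near-flat (morphine-like) profiles; grid ties are broken
toward smaller SD, then smaller T_peak, making output deterministic. If
refinement fails or worsens the grid optimum, the best grid point is
reported with a `refinement_failed` flag; a fitted SD at the upper box edge
is flagged `flat_preference` instead of being presented as a meaningful
peak. Standard errors come from the Gauss–Newton approximation
(`σ̂²·(JᵀJ)⁻¹`) with a numeric Jacobian. Degenerate inputs — fewer points
than parameters plus one, or fewer than two distinct temperatures — are
errors, not NA results.

All sums are aggregated by unique temperature first, so the per-evaluation
cost is O(number of zones) no matter how many animals are pooled.

## Nested comparisons, t tests, and planning

Group differences in one parameter use the extra sum-of-squares F test:
the null model shares only the parameter under test (e.g. a common T_peak
with group-specific SD and amplitude), the alternative fits the groups
separately, and

`F = ((SS_null − SS_alt)/(df_null − df_alt)) / (SS_alt/df_alt)`

with the p-value from the upper F tail (computed by R's regularized
incomplete-beta machinery, no tables). The shared fit reuses the same
grid/refine machinery, profiling the shared parameter on the coarse grid
before joint refinement. Degrees of freedom follow directly from point and
parameter counts (`n − 3` per 3-parameter curve, `n − 5` for the joint
null); the package documents this arithmetic and makes no attempt to match
any externally reported df that cannot be reconstructed from point counts.

Welch (heteroscedastic) and paired t tests wrap `stats::t.test` and refuse
zero-variance inputs as undefined rather than returning NaN. Cohen's d uses
the pooled residual SD `σ = sqrt((SS_a + SS_b)/(DFd_a + DFd_b))`; an
ambiguous typeset form of this quantity is sometimes seen without the
quotient and root, and the standard pooled-residual reading is implemented
and documented here. Sample-size planning defaults to the normal
approximation `n = ⌈2·(z_{1−α/2} + z_{power})²/d²⌉`, which reproduces the
assay's published design numbers (11/group at d = 1.25, 6/group at
d ≈ 1.67); the exact noncentral-t search (`method = "noncentral_t"`, via
`power.t.test`) is available and returns values at least as large. A d
computed from nonlinear-fit residuals omits between-subject variance and
can be optimistic — the planning output should be read as a lower bound,
which is also why `ge` is the right comparison for the 11/group figure.

## The simulator: what it emulates and what it does not

`simulate_track()` integrates a reflected Ornstein–Uhlenbeck process at the
frame rate: while moving,

`x ← x + k·(x_pref − x)·dt + σ_w·√dt·ξ`,  `σ_w = (SD/slope)·√(2k)·s`,

with reflection at the corridor ends. The OU process was chosen because its
stationary law is **exactly** the Gaussian occupancy the assay fits, which
makes parameter recovery a well-posed end-to-end test: the generating
`(T_pref, SD)` are the truth the fitted `(T_peak, SD)` must recover.
Rest bouts freeze the position; they are entered with hazard
`h·exp(−(T(x) − T_pref)²/(2·SD²))` per second — concentrating rest in
preferred zones, mirroring the assay's observation that resting follows
occupancy — and last Exp(mean `rest_mean_s`) seconds.

The locomotion scale `s` rescales time for the movement process: `k` by
`s²` and `σ_w` by `s`. A pure noise-amplitude scale would change the
stationary SD along with speed, conflating locomotion with preference;
time rescaling changes only how fast the stationary law is explored, so
hypo/hyperlocomotive presets (CFA, morphine) keep their printed preference
widths recoverable. When `k = 0` (flat-preference presets) the OU noise
formula degenerates, so a base diffusion amplitude
(`diffusion_cm_per_sqrt_s`, default 15 cm/√s — a realistic roaming scale
for a mouse-sized corridor) takes over, and the reflected stationary law is
uniform, giving the 100/14 ≈ 7.1 % per-zone benchmark.

Preset centers and widths are the assay's published condition parameters
(naive male 30.4/11.6 °C, naive female 32.2/13.8 °C, CFA 36.6/6.1 °C);
morphine presets are phenomenological — flat preference plus elevated
locomotion — not pharmacokinetic. Movement defaults are `k = 0.2 /s`,
rest hazard `0.05 /s`, rest mean `6 s`. Resting percentage is not a
calibrated quantity here — published values depend on an unreported
tracker immobility criterion — so the presets treat resting as qualitative
structure (where it happens, and its exponential bout law) rather than as
a target fraction, and the constants were not tuned toward any reported
percentage.

Per-animal seeds derive from the top-level seed by a counter scheme, so
cohorts are reproducible bit-for-bit and reordering or extending a cohort
never changes an existing animal's path.

What the simulator does **not** model: transverse (y) motion and
wall-following, body size (the animal is its tracked center of mass),
grooming microstructure, thermal physiology, estrous variability, and
tracking artifacts such as dropouts. Passing recovery tests therefore
demonstrates that the pipeline is statistically faithful to its own model
family — a necessary condition — but not that real mice are OU processes;
with real data the Gaussian family is an empirical approximation whose
adequacy the residual SS and flags report.

## Test design notes

Monte-Carlo checks fix their problem sizes in code: parameter recovery
uses 12 animals × 600 s per preset across 10 seeds (the assay's own cohort
scale); the uniform-occupancy check aggregates 8 driftless animals × 2 h
(a single 2-h track has ~1.3 percentage-point per-zone Monte-Carlo error,
too coarse to verify a ±1.5-point band); goodness-of-fit tests subsample
frames every ~5 OU correlation times so the chi-square reference
distribution applies to effectively independent draws; and the F-test
type-I calibration runs 1000 replicates of two identical groups drawn from
the 3-parameter model with iid zone noise — the standard parametric null
for residual-based F tests, and the only variant cheap enough to replicate
a thousand times. The resting-follows-occupancy property is asserted as a
rank correlation between the resting-by-zone and occupancy profiles rather
than as equality of their argmax zones: on a broad preference the profile
peak is a plateau, and its argmax is dominated by noise rather than by the
property under test.

## Known limitations

* Pooled-point fits treat animals as exchangeable point sources; a
  hierarchical model with per-animal random effects would propagate
  between-animal variance into the F test's denominator. The package
  follows the assay's pooled convention and says so.
* The 1-D gradient model ignores any transverse temperature variation.
* Occupancy is zone-binned by design; no continuous density estimation.
* No multiple-testing correction is applied; reports list every test run
  so users can apply their own.
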