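# tgtkit

Quantification toolkit for the **thermal gradient test (TGT)**, a
self-reported thermal-preference assay for rodents: an animal roams a long
corridor (137 cm by default) whose floor carries a stable linear temperature
gradient from 4 °C to 58 °C, and a camera tracks its center of mass at
15 frames/s. Where the animal chooses to spend its time reports thermal
preference and avoidance, and how that distribution shifts under
inflammatory pain or analgesics is the assay's readout. The package is aimed
at behavioral and preclinical pain researchers who have per-frame tracking
exports (time, position) and want the assay's statistics without hand
assembly in a spreadsheet.

## What it computes

The corridor is divided into 14 equal zones (9.8 cm each, roughly a moving
mouse's effective body length). Per animal, the fraction of analyzed frames
in each zone — the **occupancy profile** — is indexed by the zone-center
temperature through the linear calibration `T(x) = slope·x + intercept`
(nominal slope 54/137 ≈ 0.39 °C/cm). Occupancy as a function of temperature
is fit by a Gaussian preference model,

```
occupancy(T) = A · exp( −(T − T_peak)² / (2·SD²) )
```

yielding the most preferred temperature **T_peak**, the preference width
**SD**, and the **peak occupancy** (in the normalized two-parameter variant,
zone values sum to 100 % so peak occupancy is a dependent variable of SD).
Group differences in a fitted parameter are tested with the **extra
sum-of-squares F test** on nested fits (shared vs. separate parameter);
locomotion is summarized by distance traveled and immobility ("resting")
bouts longer than 3 s; and sample sizes are planned from **Cohen's d** with
a pooled residual SD, `σ = sqrt((SS_a + SS_b)/(DFd_a + DFd_b))`.

A seeded Ornstein–Uhlenbeck thermotaxis simulator generates cohorts whose
stationary position law is exactly the Gaussian occupancy the assay fits,
with condition presets (naive male/female, CFA inflammation, morphine
hyperlocomotion), so the entire pipeline is testable without animal data.

## Worked example

Simulate a naive-female cohort and a CFA (inflammatory pain) cohort, fit
both, and compare:

```r
library(tgtkit)

co_n <- simulate_cohort("naive_female", n_animals = 12, seed = 42)
co_c <- simulate_cohort("cfa",          n_animals = 12, seed = 43)

pts_n <- occupancy_points(cohort_occupancy(co_n))
pts_c <- occupancy_points(cohort_occupancy(co_c))

fit_preference(pts_n)
#> Gaussian preference fit (free_3p): T_peak = 31.57 +/- 0.34 C, SD = 12.80 +/- 0.36 C
#>   peak occupancy 12.4%; SS = 618.771 on 165 df (n = 168)
fit_preference(pts_c)
#> Gaussian preference fit (free_3p): T_peak = 37.03 +/- 0.19 C, SD = 5.21 +/- 0.19 C
#>   peak occupancy 29.2%; SS = 2725.179 on 165 df (n = 168)

compare_preference(pts_n, pts_c, "t_peak")
#> Extra sum-of-squares F test: F(1, 330) = 74.81, p = 2.304e-16
```

The CFA cohort's preference is warm-shifted (T_peak 37.0 °C vs 31.6 °C) and
sharply narrowed (SD 5.2 °C vs 12.8 °C) — the inflamed animals avoid the
thermal extremes and concentrate near body temperature, which is what the
assay detects as a pain phenotype. Each fit pools 12 animals × 14 zones =
168 points; the F test has 1 and 330 degrees of freedom because the
alternative model fits 3 parameters per group.

Sample-size planning for a 1.5 °C detectable shift with a 1.2 °C
within-group SD:

```r
run_power(1.5, 1.2)
#> Effect size: delta = 1.5, pooled sigma = 1.2, d = 1.25
#> n per group: 11
```

For file-based workflows, `run_simulate()`, `run_analyze()` and
`run_compare()` read/write the trajectory CSV dialect
(`animal_id,time_s,x_cm`), occupancy/activity CSVs and JSON fit reports; a
thin command-line wrapper lives at `inst/cli/tgt.R`.

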