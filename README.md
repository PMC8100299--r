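# qaradar

Quantified activity assessment from multi-sensor impulse-radar (IR-UWB)
recordings, and functional-ANOVA comparison of group activity curves.

## What problem this solves

Objectively quantifying how much a person moves — for example, hyperactivity
in children during a continuous attention task — is hard with subjective
ratings, and camera- or accelerometer-based tools each miss classes of
movement. Impulse-radio ultra-wideband radar senses *any* change in the echo
path, contact-free. This package is for researchers who want to (a) turn raw
multi-sensor radar frames into interpretable per-minute activity scores and
(b) test whether two groups' activity *curves over time* differ, which is far
more sensitive than comparing session totals.

## The method

A received frame from sensor *i* is a superposition of delayed pulse echoes
plus noise, `x_i[k] = Σ_m a_{m,i} s[k − τ_{m,i}] + N[k]`. Per sensor and
frame *n*:

1. adaptive clutter removal — `C_n = α C_{n−1} + (1−α) x_n`, `y_n = x_n − C_n`
   (default α = 0.97);
2. Hilbert envelope `A_n[k] = |y_n[k] + j·H(y_n)[k]|`;
3. movement mask `g_n[k] = 1` iff `|A_n[k] − A_{n−1}[k]| ≥ T_i`, with `T_i`
   calibrated as mean + 3·SD of pooled envelope differences from an
   empty-room recording;
4. per-frame count `Q_i[n] = Σ_k g_n[k]`, fused across the four sensors by
   the **median**;
5. averaged in one-minute blocks → 22 per-minute scores per 22-minute
   session; their sum is the total activity.

Group curves (one score per minute per subject) are interpolated by natural
cubic splines on a 221-point grid and compared under
`H0: μ1(t) = μ2(t)` with two statistics — the **globalized pointwise F**
(time-average of the pointwise two-group ANOVA F) and **F-max** (its
supremum) — using a group-label permutation null (add-one rule, default
B = 1000). The same machinery applies to the spline derivatives ("velocity"
curves). Pointwise distributions at selected minutes, areas under curves,
Wilcoxon rank-sum and Spearman correlations complete the analysis surface.

A synthetic module simulates the whole measurement: pulse templates, clutter,
per-frame delay jitter driven by a movement-intensity trajectory (flat
control group; case group rising after minute 7 with inflated dispersion),
and empty-room recordings for calibration.

## Worked example

Score a simulated 6-minute recording with a rising movement trend:

```r
library(qaradar)
radar <- radar_config(n_sensors = 4, fps = 20, n_bins = 64)
scene <- default_scene(radar, seed = 1)
prof  <- trajectory_profile("ADHD", baseline_intensity = 0.5,
                            trend_per_minute = 0.3, changepoint_minute = 2,
                            duration_minutes = 6, noise_sd = 0.1)
traj  <- simulate_trajectory(prof, radar$fps, seed = 2)
rec   <- simulate_recording(scene, traj, radar, seed = 3, jitter_gain = 1)
empty <- simulate_empty_room(radar, 2000, seed = 4, scene = scene)
qs    <- process_recording(rec, calibrate_threshold(empty))
round(qs$minute_scores, 1)
#> [1] 6.5 6.5 7.5 7.6 8.2 9.6
```

The scores (median count of range bins changing beyond threshold, averaged
per minute) sit near 6.5 while the subject is calm and climb once the
trajectory starts rising after minute 2.

Compare the default synthetic cohort (10 cases vs 15 controls, 22 minutes):

```r
coh    <- simulate_cohort(cohort_config(seed = 42), curves_only = TRUE)
curves <- build_curves(coh$curves, coh$labels)
fanova_tests(curves, n_resamples = 1000, seed = 7)
#> $gpf
#> GPF test (activity curves): statistic = 5.1960, p = 0.01798 (1000 permutations)
#> $fmax
#> Fmax test (activity curves): statistic = 19.0408, p = 0.000999 (1000 permutations)

totals <- rowSums(coh$curves)
scalar_group_compare(totals, coh$labels$group)
#> [1] 0.05566
```

Both functional tests detect the late-session divergence of the case group's
mean curve, while the rank-sum test on session *totals* misses it at
α = 0.05 — the temporal pattern, not the total amount of movement, separates
the groups.

A command-line front end wraps the same functions
(`system.file("cli", "qar", package = "qaradar")`): `qar simulate`,
`qar process`, `qar analyze`, `qar run`.

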