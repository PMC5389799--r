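---
title: "Quantifying neurotransmitter flux from extracellular 13C enrichment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neurotransmitter flux from extracellular 13C enrichment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecflux)
```

## The measurement problem

When [2,5-¹³C]glucose is infused intravenously, glycolysis and the TCA
cycle place ¹³C predominantly at C5 of brain glutamate. Neurotransmitter
glutamate released from neurons into the extracellular fluid (ECF) carries
this label, so the *rate* at which extracellular glutamate (GLU~ECF~)
becomes ¹³C-enriched at C5 reports the flux of glutamate from neurons to
ECF — a quantity a concentration measurement alone cannot separate from
uptake. The same logic applies to extracellular glutamine (GLN~ECF~), the
product of glial uptake and glutamine synthetase, one turn downstream in
the glutamine/glutamate cycle.

The raw data are microdialysis fractions collected from awake animals:
each fraction has an HPLC concentration (µM) and, after tBDMS
derivatization, selected-ion-monitoring (SIM) GC-MS peak areas for a set
of light/heavy (M/M+1) ion pairs. `ecflux` turns these into per-subject C5
enrichment time courses, per-subject enrichment rates, and group-level
statistics, and ships a synthetic-cohort generator so the whole chain is
verifiable by parameter recovery.

## From peak areas to fractional enrichment

For an ion pair with light-ion area $B$ and heavy-ion area $A$, part of
the M+1 signal is natural abundance, not biology. With correction factor
$C$ (the expected $A/B$ from naturally occurring heavy isotopes alone),
the biological fractional enrichment is

$$E = \frac{A/B - C}{1 + (A/B - C)}.$$

$C$ is computed from the fragment's elemental composition as the linear
sum $\sum_e n_e p_e$ of atom counts times M+1 abundances
(`mplus1_fraction()`, default abundances ¹³C 0.0110, ²H 0.00015, ¹⁵N
0.0037, ¹⁷O 0.0004, ²⁹Si 0.047). The linear sum — rather than the exact
single-substitution expansion $\sum_e n_e p_e/(1-p_e)$, available via
`method = "exact"` — is the default because it is the convention under
which the packaged factors for the glutamate and pyroglutamate fragments
(0.362, 0.278, 0.234; 0.245, 0.234, 0.161) were derived; the two methods
differ by under 1% except for silicon-rich tBDMS fragments, where ²⁹Si
(4.7%) makes the exact form up to ~5% (relative) larger. When an ion-pair
table supplies both a composition and an explicit factor, the explicit
factor wins; the composition is kept as a cross-check.

The m/z 330 glutamate fragment is recorded with its printed composition
C₁₆H₂₁NO₂Si₂. Its nominal mass (315) suggests the hydrogen count is
understated (H₃₆ gives 330), but hydrogen contributes less than 0.006 to
the factor, so either count yields 27.8% at the reported precision; both
are documented with the packaged table.

Enrichments from the two C2–C5 pairs of each analyte are averaged;
a spread above 0.01 (the ±1% concordance expected between pairs) raises a
`discordant` flag without discarding the value. Ratios below $C$ produce
*negative* enrichments which are retained and flagged `below_baseline`
rather than truncated — truncation at zero would bias averages and rate
fits near the start of infusion, where true enrichment is ~0 and noise is
symmetric.

## Positional C5 enrichment and label scrambling

The monitored fragments cover C2–C5, but prolonged infusion scrambles
label into C2–C4 via TCA-cycle turnover (and, for glutamine, the
glia-specific pyruvate-carboxylase route into C2/C3). The scrambling
ratio $\rho(t)$ — the fraction of the aggregate C2–C5 enrichment residing
at C2+C3+C4 — is modeled piecewise linearly with $\rho(0)=0$:
0.00089 min⁻¹ for glutamate, and 0.0016 min⁻¹ to 120 min then
0.00042 min⁻¹ afterwards for glutamine (NMR-calibrated; the glutamate
slope is recovered by a through-origin least-squares fit of the two
calibration ratios, 0.098 at 2 h and 0.198 at 3.6 h — through the origin
because no scrambled label can exist at infusion start, and only that
constraint reproduces the calibrated slope from two points).

Because $\rho$ is a *fraction of* the aggregate enrichment, the
correction is multiplicative,

$$E_{C5}(t) = E_{C2\text{–}C5}(t)\,\bigl(1 - \rho(t)\bigr),$$

not a subtraction of $\rho$ itself, which would subtract a dimensionless
ratio from an enrichment. Beyond 180 min the last slope extrapolates and
the series row is flagged `extrapolated`. $\rho$ is evaluated at each
fraction's reported time (below); the calibration itself cannot resolve
finer timing.

## The microdialysis clock

Fractions are collected in 15-min windows for 1 h before infusion, then
5-min windows for 3 h. Dialysate needs 180 s to travel from probe to
vial, so the reported (brain-time) stamp of a fraction is its window
midpoint minus the dead time (`reported_time()`; disable by setting
`dead_time_s = 0` if your acquisition already corrects it). t = 0 is the
start of tracer infusion; pre-infusion fractions have negative reported
times, define the enrichment baseline (zero) and the concentration
baseline (100%). Before GC-MS, 2–3 consecutive 5-min fractions are pooled
(areas add; concentrations average under the constant 2 µL/min flow). The
packaged pooling plan alternates pools of 3 and 2 fractions, which places
pooled reported times at 4.5, 17, 29.5, 42, 54.5, **67**, … min — so the
glutamine comparison point at 67 min is measured exactly.

## Rates and statistics

The enrichment rate of each subject is the slope of the ordinary
least-squares line through the (reported time, $E_{C5}$) points inside
the analyte's fit window — 0–120 min for glutamate and 0–110 min for
glutamine, which rises linearly to ~110 min and then levels off. The
intercept is free: the published procedure fits "the least-squares line",
and a free intercept is robust to baseline noise and to an early offset
in the trajectory (a through-origin variant exists for sensitivity
analysis). Rates are summarized per group as mean ± SE (SD/√n).

Group comparisons use one-way ANOVA plus *both* post-hoc tests the field
uses here — Scheffé ($F' = \Delta^2 / (\mathrm{MSW}(1/n_i + 1/n_j))$
against $(k-1)F_{\mathrm{crit}}$) and Tukey HSD in the Kramer unequal-n
form ($q = |\Delta| / \sqrt{\tfrac{\mathrm{MSW}}{2}(1/n_i + 1/n_j)}$
against the studentized range, with critical values from the distribution
function, not a table) — since the original software reported whichever
established significance per endpoint. `anova_from_summary()` rebuilds
the F test from printed means/SEs/ns; note that rounded summaries can
inflate F noticeably (the three-group rate comparison gives F ≈ 39 from
rounded summaries versus 27.0 from raw data), so it is a consistency
tool, not a reanalysis. Per-time-point ANOVAs across groups carry no
multiplicity correction across time points, mirroring the original
analysis; treat isolated per-time-point significances with caution.

Seizures enter the analysis only as group labels: an electrographic
seizure is a run of abnormal EEG activity persisting strictly longer than
10 s (`events_from_mask()`; shorter runs are inter-ictal spikes), and a
kainate-treated subject with ≥ 8 seizures in the 3-h window is classified
"frequent", 1–7 "infrequent". The cutoff of 8 is this package's choice —
the midpoint of the two observed group means (5.0 and 10) — and is
configurable (`seizure_cutoff`); the original report defines the groups
by their observed counts without stating a threshold.

## What the synthetic generator emulates

`simulate_cohort()` forward-models the full study: three groups (6
controls, 6 infrequently seizing, 4 frequently seizing), per-subject true
slopes drawn around the group means with between-subject SD
reconstructed from printed SEs as SE·√n, baselines drawn mean-preserving
lognormal (Table-level SEs imply large CVs and concentrations must stay
positive), seizure counts Poisson conditioned to ±3 of the group mean
with uniform onsets, 74%/26% hypersynchronous/low-voltage-fast onset
types, and durations 15–90 s.

Enrichment truth is linear in reported time, $E_{C5}(t) = a + b_i t$
(glutamine capped at its 110-min plateau), with $a = 0$ except for
frequently seizing glutamine, where $a = 0.23 - 0.00299 \times 67 \approx
0.0297$ pins the group mean at the observed 0.23 at the 67-min fraction
while leaving the fitted slope at 0.00299 min⁻¹ (the free intercept of
the rate fit absorbs $a$); this reproduces the early elevation of that
group's time course. The aggregate truth is $E_{C5}/(1-\rho(t))$ — the
exact inverse of the positional correction — and peak areas are generated
from the *pooled-center* truth for all members of a pool, so that a
noiseless cohort closes the pipeline exactly (recovered slopes and
endpoints equal the presets to machine precision, a property the test
suite asserts). Measurement noise is multiplicative mean-one lognormal
with CVs 5% (enrichment), 10% (concentration) and 2% (peak areas),
chosen so single-subject slope SEs match the scatter of the published
time courses.

Glutamate concentration truth interpolates absolute knots scaled to each
subject's baseline (frequently seizing: flat to 80 min, 3.1 µM at
120 min, 3.3 µM at 125 min — the 120/125-min values read qualitatively
from the published time course — then 5.51 µM at 167 min and constant
after). Glutamine concentration truth declines linearly in
percent-of-baseline from 100% at t = 0 to the group endpoint (100%,
77.1%, 66.2%) at 170 min, constant after, so the final 5-min fraction
(reported 174.5 min) measures the endpoint exactly.

The generator does **not** emulate: seizure→enrichment coupling within a
subject (group structure only, as in the original group-level analysis),
probe recovery calibration, chromatographic peak integration, drift or
heteroscedastic detector noise, or mechanistic glutamine/glutamate-cycle
kinetics. Passing recovery tests therefore demonstrates correctness of
the estimation chain under the study's design and noise magnitudes, not
robustness to every artifact of real chromatograms.

## Numerical choices and problem sizes

Degenerate inputs fail loudly: non-positive light areas, ratios at or
below the $1 + (A/B - C) = 0$ pole, fewer than 3 points in a fit window,
zero time variance, groups of n < 2, zero within-group variance (ANOVA
reports an infinite-F sentinel with a `degenerate` flag). Ion-pair
concordance uses an absolute 0.01 tolerance. The recovery studies in the
tests and in `scripts/acceptance.R` use 200 replicate cohorts — enough to
pin group means to a relative SE below 1% — and complete in a few minutes
on one core; `recovery_study()` takes `n_reps` if you want tighter
Monte-Carlo error.

## Known limitations

C1 enrichment is not modeled (the C2–C5 fragments exclude it, and the
C1–C5 pairs are carried for QC, not reporting). The scrambling
calibration rests on two NMR time points per analyte; its uncertainty is
not propagated into the C5 series. Whether the per-subject rate fits of
the original analysis used pooled-fraction or nominal 5-min times is not
stated; this package uses the pooled, dead-time-corrected reported times
throughout.
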