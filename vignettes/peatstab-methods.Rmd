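---
title: "Methods: simulating and analysing peat-moss drawdown experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing peat-moss drawdown experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peatstab)
```

## The experiment being modelled

A two-species *Sphagnum* replacement series: 40 peat cores spanning five
cover compositions of *S. cuspidatum* against *S. medium* (100/0, 75/25,
50/50, 25/75, 0/100 %), each composition split over two water table
drawdown arms (n = 4). Both arms share an acclimation period and a 7-day
mild drawdown (−5 cm); the deep arm continues for 14 further days at
−25 cm; both end with an 8-week rewetting (recovery) period. Net ecosystem
CO₂ exchange (NEE, µmol CO₂ m⁻² s⁻¹, uptake positive) is measured by
closed transparent chamber: three times during acclimation (11, 9 and 1
days before drawdown), four times per week during drawdown, twice per week
during recovery.

`phase_schedule()` encodes this calendar with day 0 at the start of the
measured acclimation window and drawdown starting on day 11, so the mild
arm's recovery runs from day 18 and the deep arm's from day 32. Measurement
days are deterministic given the schedule (drawdown weeks at offsets 1, 3,
5, 7; recovery weeks at offsets 3, 7) so that simulations are exactly
reproducible; day-jitter is deliberately not simulated.

## The synthetic NEE generator

`generate_nee_series()` draws, for each mesocosm and scheduled day,

NEE(d) = L_p + s_p · (d − start_p) + ε,  ε ~ N(0, σ²) i.i.d.,

where `s_p` is the phase trend of the mesocosm's (mixture, treatment,
phase) cell and `L_p` the phase-entry level. Entry levels are continuous
with the previous phase's noiseless end value, with one exception: at
rewetting a configurable step applies. The generator is phenomenological —
it reproduces the statistical structure the downstream analysis assumes
(piecewise-linear phase trends, homoscedastic measurement noise,
replicate-to-replicate independence), not the physics of water tables,
evaporation or moss physiology, and no CH₄/H₂O channels.

Defaults, and why:

* **Baselines** (`default_baselines()`): 1.35, 1.25, 1.15, 1.05, 0.95
  µmol m⁻² s⁻¹ in design order. Acclimation NEE in such mesocosms spans
  roughly 0.74–1.71 µmol m⁻² s⁻¹, with monoculture *S. cuspidatum* highest
  and *S. medium* lowest overall; an evenly spaced ladder inside that range
  encodes the ordering without asserting unreported per-mixture values.
* **Drawdown trends** (`default_phase_slopes()`): the published
  per-mixture response slopes — mild 0.20, 0.14, 0.21, 0.14, 0.19; deep
  −0.18, −0.11, −0.11, −0.13, −0.09 — interpreted as µmol m⁻² s⁻¹ per
  day. The units are not printed with the source table; per-day units are
  the only reading consistent with a ~doubling of NEE over the 7-day mild
  week, and are flagged here for users comparing magnitudes. Acclimation
  trends are 0 (NEE is stationary before drawdown).
* **Recovery trends**: small positive rates, 0.003 d⁻¹ in the mild arm
  (recovery-period change there is marginal) and 0.009…0.003 d⁻¹ in the
  deep arm, decreasing with *S. medium* share (recovery after deep
  drawdown is faster for ≥ 75 % *S. cuspidatum*). Directions are reported
  findings; magnitudes are this package's choice since none are printed.
* **Rewetting step**: the mild arm shows an immediate drop in NEE on
  rewetting, to slightly below pre-drought levels; the deep arm does not.
  Default: mild arm `reset` mode with offset −0.1 (entry level = baseline
  − 0.1), deep arm `continuous` with offset 0. Both mode and offset are
  configuration, not hard-coded, because only the direction of the step is
  reported. Whether the mild-arm step should default on was an open call;
  it defaults **on** because the drop is described as immediate and
  consistent, and turning it off is a one-line config change.
* **Noise** `noise_sd = 0.4` µmol m⁻² s⁻¹. Only group-level slope standard
  errors are available to calibrate against. With mild-phase measurement
  days at offsets {1,3,5,7}, the design sum of squares is Sxx = 20 and the
  SE of a group mean slope over n mesocosms is σ/√(20·n): σ = 0.4 gives
  0.032 at n = 8, inside the published mild band (0.03–0.05). The deep
  phase (Sxx = 148.1) then gives 0.016 at n = 4, inside the deep band
  (0.01–0.04). The constant was fixed from this closed-form calculation.
* **Missingness**: one deep-arm 75/25 mesocosm is removed before analysis
  (`apply_missingness()`), reproducing the unit lost to a leaking
  container; every downstream stage tolerates the resulting n = 3 cell.

Within-day replicate structure is not simulated: one chamber placement per
mesocosm per measurement day, which is how such campaigns are usually run
and all the analysis needs. Heat events around the drawdown transitions are
schedule annotations in the real experiment and have no simulated thermal
effect.

## Chamber fluxes

`trace_to_nee()` fits an ordinary least-squares line to the chamber CO₂
record after discarding a 30 s dead band (chamber-closure artefacts), then
converts the ppm s⁻¹ slope `s` with the ideal gas law: the chamber holds
`n = PV/(RT)` mol of air (R = 8.314 J mol⁻¹ K⁻¹), so

NEE = −s · n / A = −s · PV / (R·T·A),

normalised to the mesocosm (collar) surface `A = π(0.225/2)²` m² — the
moss surface the flux crosses — not the chamber cross-section. The sign
flip implements the ecological convention (uptake positive). Defaults:
chamber ∅ 0.29 m × 0.30 m (V = 0.0198 m³), 295.15 K, 101325 Pa, all
overridable; an `extra_volume` field can add loop tubing volume, which is
excluded by default because it is not measurable from the design
description. Traces with r² < 0.75 are flagged, never dropped: no
rejection rule is reported, and flagging preserves data. Water-vapour
dilution is not corrected — a documented limitation; fluxes from very
moist chambers will be slightly biased. Fixed-window OLS after the dead
band is used throughout; automatic sub-window selection (as some flux
packages offer) is out of scope.

`generate_concentration_trace()` is the exact inverse map, so noiseless
traces round-trip through `trace_to_nee()` to the generating NEE within
1e−9 (property-tested over random geometry, temperature and pressure).

## Stability statistics

Per mesocosm (`summarize_mesocosm()`):

* `nee_acc_mean` — mean over all acclimation measurements;
* `nee_d` — mean NEE on the **final measurement day** of the arm's
  drawdown (mild arm: end of mild phase; deep arm: end of deep phase).
  A day-mean rather than the literal last reading makes the statistic
  robust to accidental duplicate records; on the standard schedule they
  coincide;
* `nee_rec` — mean NEE on the final recovery measurement day;
* resistance Ω = `nee_acc_mean / (nee_d − nee_acc_mean)`, **signed**
  (drawdown can move NEE either way, so the magnitude-only variant of the
  source stability framework would discard the direction); Ω = 1 is a
  doubling, Ω = −2 a halving, |Ω| large means high resistance;
* resilience Δ = `|(nee_d − nee_acc_mean) / (nee_rec − nee_acc_mean)|`,
  ≥ 0, large when NEE has returned close to baseline;
* response slopes: within-phase OLS of NEE on day, day re-zeroed to the
  phase start so slopes are comparable across arms whose phases start on
  different calendar days. The deep arm's `drawdown_slope` is its
  deep-phase slope (its mild-week slope is reported separately as
  `slope_mild`) — the two phases have opposite trends, so a pooled
  "full drawdown" slope would estimate neither; `recovery_rate` uses all
  recovery measurements, not endpoints.

Degenerate denominators (unchanged NEE for Ω, full return for Δ) are
detected at a tolerance of 1e−9 on the µmol m⁻² s⁻¹ scale and returned as
`Inf` with `omega_infinite` / `delta_infinite` flags. Group-level tests
exclude flagged values listwise, with counts carried in the run log —
infinities must not propagate into ANOVA sums.

## Group inference

The implemented inference surface is the slope-ANOVA path that the
response-slope table rests on: per-mesocosm slopes, then
`group_slope_table()` (mild phase pools both arms, n = 8, because the
hydrology is identical over that week; deep phase uses the deep arm only),
`oneway_anova()` computed from the between/within sum-of-squares
decomposition with the p-value from the F distribution, and
`pairwise_contrasts()` — Tukey HSD via the studentized range distribution
with Tukey–Kramer standard errors for unbalanced cells. No further
multiplicity layer is added beyond Tukey. `align_recovery()` re-indexes
recovery days to each arm's rewetting start for pooled recovery analyses;
it keeps the calendar day and is idempotent.

`fit_phase_lmm()` refits the phase-wise repeated-measures mixed model
(treatment × mixture × day fixed effects, random mesocosm intercept) as a
convenience output via `lmerTest`. The random-effects structure of the
original analyses is not fully specified anywhere, so this model documents
its own structure and claims no equivalence; on near-noiseless simulated
data the random-intercept variance can fit to zero (a harmless singular
fit).

## Numerical and testing choices

Degenerate ANOVA layouts return explicit markers (`F = Inf`, p = 0 when
within-group variance is zero; `F = 0` when all values are equal) rather
than NaN. OLS goes through `stats::lm`; tests verify it against an
independently coded centered-sums closed form to 1e−12 (absolute — slopes
near zero make relative comparisons meaningless), and the ANOVA against a
raw-totals sum-form recomputation to 1e−10 plus exact SS conservation.
Tukey p-values are cross-checked against `stats::TukeyHSD` to 1e−6.

Test problem sizes are chosen to keep the suite fast while leaving Monte
Carlo error well below the asserted bands: 50 mesocosms for slope-recovery
checks (SE of the mean recovered deep slope ≈ 0.005, against a ±0.02
band), 100–200 replicate experiments for power and type-I-error checks at
the study's n = 4, and 100 random draws for round-trip and oracle
properties.

What passing tests show — and what they do not: the suite demonstrates
that the pipeline recovers known generative truth under the generator's
assumptions (linear phase trends, i.i.d. Gaussian noise, no within-day
replication, no serial correlation). Real chamber campaigns violate some
of these — serially correlated weather-driven deviations, heteroscedastic
noise, drifting baselines — so passing here validates the computations,
not the field applicability of the linear-trend model itself.
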