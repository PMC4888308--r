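---
title: "Pre-shot ERD/ERS analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-shot ERD/ERS analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Elite precision-sport athletes reach good results through more than one
processing mode: sometimes execution is fluent and automatic, sometimes
it is deliberately controlled. The multi-action-plan (MAP) framework
crosses performance level (optimal / suboptimal) with action control
(automatic / controlled) into four performance states, Type 1
(optimal-automatic) through Type 4 (suboptimal-automatic). The question
this pipeline addresses is whether the seconds of EEG preceding each
shot carry state-specific oscillatory signatures: event-related
desynchronization (ERD, a band-power decrease against a pre-shot
baseline) or synchronization (ERS, an increase) in the theta (4--8 Hz),
low-alpha (8--10 Hz) and high-alpha (10--12 Hz) bands.

`preshot` implements that analysis end to end — epoching, artifact
handling, Hilbert-envelope band power, ERD/ERS% maps per performance
quadrant, and electrode-wise repeated-measures ANOVA — together with a
synthetic-session generator that injects *known* band-power modulations,
so every stage can be verified quantitatively even though no raw
shooting-EEG data set is publicly deposited.

## The ERD/ERS model

For each epoch (a 10-s window from $-6$ to $+4$ s around shot release,
half-open at $+4$), each channel is band-pass filtered per band and the
instantaneous power is taken as $|a(t)|^2$, the squared magnitude of the
analytic signal. Note the convention: a unit-amplitude sine has envelope
power $A^2 = 1$, not $A^2/2$; every oracle in the test suite uses the
same convention, so no factor-of-two ambiguity survives.

Within each (subject, performance type, band) group the baseline power
$P_{base}$ per channel is the mean of instantaneous power over the
group's epochs and over the $[-5, -4)$ s window. Baselines earlier than
$-5$ s are disallowed: that far from the shot, posture adjustments and
respiration contaminate the signal. For the three 1-s intervals of
interest $[-3,-2)$, $[-2,-1)$, $[-1,0)$ the per-epoch index is

$$\mathrm{ERD/ERS\%} = -100\,\frac{P_{int} - P_{base}}{P_{base}},$$

so a power *decrease* gives a positive value (ERD) and an increase a
negative value (ERS). The literature states this definition both ways;
the sign here matches how the published statistics mark
synchronization-dominant states with negative percentages, and a
`sign_convention = "raw_percent_change"` switch yields the plain percent
change instead. Per-epoch maps are averaged within (subject, type), and
grand averages across subjects weight subjects equally regardless of how
many epochs each contributed. Averaging per-epoch indices (rather than
averaging power first) is the default; `average = "power_first"` is
exposed for sensitivity checks.

Baseline pooling is per (subject × type), the finest grouping consistent
with group-wise baseline averaging; pooling per subject overall would
mix states whose baseline power may itself differ.

## Preprocessing

The broadband filter is a zero-phase (forward--backward) Butterworth,
4th-order high-pass at 0.3 Hz plus 4th-order low-pass at 40 Hz. The
order is deliberately moderate: a high-pass at 0.3 Hz is numerically
delicate, and the theta/alpha bands sit far from both edges (gain within
5% of unity at 10 Hz; about $-17$ dB at 50 Hz after the double pass).
Epochs are cut with the uniform `round(onset × fs)` sample convention;
the sample at relative time 0 is exactly the shot-release sample, a
property pinned by an impulse-alignment test.

Artifact handling replaces interactive visual inspection with
transparent threshold rules, applied only to the analysis-relevant
pre-shot span $[-6, 0]$ s: an epoch is rejected when any channel exceeds
100 µV peak-to-peak, exceeds 50 µV/sample gradient, or is flat below
0.5 µV peak-to-peak. Post-shot recoil artifacts therefore never discard
a trial. No correction (ICA, regression) is attempted: rejection is
reproducible, correction quality is not. No re-referencing is applied;
data stay in the recording reference, and the ERD/ERS index is invariant
to any per-channel scaling anyway (a tested property).

## Quadrant categorization

Trials map to MAP quadrants by crossing *optimal* (shooting score
$\ge$ 10.2 on the 0--10.9 scale) with *automatic* (perceived control
$\le$ 4 on the 0--11 Borg scale). The sources state the score boundary
both as "from 10.2" and "> 10.2"; the closed form ($\ge$, $\le$) is the
more explicit statement and is used as the default, with both closures
exposed as configuration. A `median_split` mode derives the two cut-offs
from the data instead — pooled across subjects by default (one rule for
all athletes), or per subject. The published per-type descriptive table
reports a mean control of 4.59 for Type 1, *above* the ≤ 4 automatic
cut-off; that inconsistency (possibly a per-subject split in the
original analysis) cannot be resolved from the published record, so both
modes are provided and no intent is guessed.

## The statistics

Per (band, electrode), subject × type × interval cell means enter a
4 × 3 within-subject ANOVA. Sums of squares partition into subjects, A
(performance), A×S, B (time), B×S, A×B and A×B×S, each within-effect
tested against its own subject-interaction term. With 10 subjects the
uncorrected degrees of freedom are (3, 27), (2, 18) and (6, 54). The
implementation is checked against two independent oracles: a
projection-matrix brute force (Kronecker products of centering
operators, to 1e-10) and `aov()` error strata.

Sphericity is assessed per effect with Mauchly's test on the
orthonormal-contrast covariance $M$; Greenhouse--Geisser
$\hat\varepsilon = \mathrm{tr}(M)^2 / (p\,\mathrm{tr}(M^2))$ with $p$
the effect's numerator df, and Huynh--Feldt
$\tilde\varepsilon = \min\!\big(1, (n p \hat\varepsilon - 2)/(p(n - 1 -
p\hat\varepsilon))\big)$. The default policy applies Huynh--Feldt
df-scaling only when Mauchly's p < .05 ("mauchly-gated"), with
`always` and `never` modes for sensitivity; reported dfs are always the
uncorrected integers with the epsilons alongside, mirroring how such
tables are conventionally printed. One caveat found while validating:
"corrected p ≥ uncorrected p" holds in the rejection-relevant region
but *inverts* for F ≲ 1 — a property of the F distribution, so the test
suite asserts the inequality only for F ≥ 1.5.

Effect size is partial eta squared,
$\eta_p^2 = F \cdot df_1 / (F \cdot df_1 + df_2) =
SS_{effect}/(SS_{effect}+SS_{error})$. Fisher LSD post-hocs
(unadjusted pairwise t-tests on marginal means, using the effect's own
error term and df) run only after a significant omnibus effect — the
classical LSD protection. No correction is applied across the 96
electrode × band ANOVAs by default, matching the analysis the pipeline
models; a Benjamini--Hochberg option exists but is off.

With fewer subjects than an effect's contrast dimensions (n − 1 < p) the
contrast covariance is singular: the epsilons still follow the trace
formulas (no inversion needed) but Mauchly's test is reported `NA` with
a warning. Degenerate tables (error MS = 0) flag F as `NA` rather than
dividing by zero.

## The synthetic generator

Each channel is a sum of three band oscillators plus $1/f^\alpha$
Gaussian background noise ($\alpha = 1$ by default, `noise_sd` 3 µV).
An oscillator is an amplitude-modulated sinusoid at the band's centre
frequency (6, 9, 11 Hz) with a slow random phase drift (per-sample SD
0.01 rad, keeping instantaneous frequency well inside the band). This is
the minimal signal model whose band power is exactly controllable.

Modulation: within each designated 1-s pre-shot window the oscillation
amplitude is multiplied by the configured gain $g$; inside the
$[-5,-4)$ s baseline it always equals the baseline amplitude. Gains act
on *amplitude*; the ground-truth index is in *power*,
$100(1 - g^2)$ — stated explicitly to avoid the classic
amplitude-vs-power factor confusion. Transitions use 100-ms raised-
cosine ramps placed just outside the window, because step modulation
splatters broadband energy into neighbouring bands; the plateau covers
the whole scored window. Per-subject, per-channel amplitude
heterogeneity (±10%) makes grand averaging non-trivial without touching
the indices (scale invariance).

Defaults are the study conditions the generator emulates: 10 subjects,
120 shots each, 1024 Hz, the 32-channel 10--20 cap, ~60 s between shots,
quadrant mixture (238, 350, 212, 348)/1148, and per-quadrant behaviour
distributions with the published means/SDs. Where the published record
gives no power-units effect size, default gains follow the reported
*direction* only — alpha ERS ($g>1$) for the automatic states (Types 1
and 4), alpha ERD ($g<1$) for the controlled states, theta ERD confined
to Type 3 — with magnitudes (0.80--1.15) chosen once as a plausible
moderate modulation; no magnitude claims are made.

Behaviour draws are truncated normals confined to each quadrant's region
under the fixed rule, so categorization recovers the generating state
exactly. For Types 2/3 (and all scores) the published means are
region-consistent and are reproduced; for Type 1/4 *control* the
published means sit above the automatic cut-off (the inconsistency noted
earlier), so draws are truncated at 4 and their realized means fall near
3.8 — the one place the generator departs from the published
descriptives, by necessity.

Artifacts: a Poisson process (default 1/min) of ocular transients
(blink-like 200--350 µV slow deflections, strongest frontopolar,
decaying to zero posteriorly) and muscular bursts (broadband noise,
60 µV SD, on a random 30% channel subset). Each event is logged with
onset/duration/type, so detection recall is measurable (≥ 0.9 at default
thresholds in the test suite). The generator does *not* model volume
conduction, realistic EOG/EMG morphology, non-stationary background
spectra, or inter-channel correlation — so passing tests demonstrate
correct *signal processing and statistics*, not robustness to every
physiological confound of real recordings.

## Numerical choices and problem sizes

* Band and broadband filters: zero-phase 4th-order Butterworth;
  band-power edge guard 0.5 s at each epoch end excluded from all
  window statistics.
* Sample addressing: `round(seconds × fs)` everywhere (never floor).
* EDF I/O: 16-bit with a symmetric physical range chosen from the data
  (round-trip error below (range)/2^16); recordings that are not a
  whole number of 1-s records are zero-padded on disk with the true
  sample count kept in the reserved header field.
* Topographic maps: inverse-distance-weighted interpolation (power 2)
  on an azimuthal-equidistant projection, exact at electrode sites,
  masked outside the electrode hull; montage positions are constructed
  from the 10--20 geometry itself (10%/20% steps along great-circle
  arcs), so homologous sites mirror exactly. Spherical splines would be
  smoother but need more machinery; IDW suffices for qualitative maps.
* Verification sizes (chosen to keep the whole suite in minutes):
  gain-recovery sessions use 1 subject × 240--280 trials at 256 Hz with
  4 channels and 14-s spacing (≥ 50 epochs per type); the type-I
  calibration uses 500 null index tables at the full 10 × 4 × 3 design;
  the demonstration analysis in `analysis/` uses 2 subjects × 60 trials
  at 256 Hz with 16 channels. The generator's *defaults* remain the
  full study conditions.

```{r recovery-example}
library(preshot)
# injected amplitude gains are recovered as ERD/ERS% within +/-5 points
res <- recovery_experiment(gains = c(0.6, 0.8, 1.0, 1.25),
                           n_trials = 280, seed = 301)
aggregate(cbind(recovered, expected) ~ gain, res, mean)
```

## Known limitations

* ERD/ERS values, F statistics and post-hoc tables of any particular
  real data set cannot be reproduced here, because no raw shooting EEG
  is deposited; the acceptance layer therefore combines exact
  reproduction of statistics that depend only on printed inputs (df
  arithmetic, effect-size identities) with property-based verification
  on synthetic data.
* Eight of the 47 published effect rows are internally inconsistent
  (their printed η²p does not match their own F and dfs); only the 39
  self-consistent rows are used as identity checks.
* The threshold artifact detector is tuned to the generator's artifact
  morphology; real ocular/muscular activity is more varied, and a
  practitioner would complement it with visual review or ICA.
* Unbalanced epoch counts are handled by cell-mean reduction before the
  ANOVA; mixed-effects alternatives are out of scope.
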