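---
title: "Detecting facility-level measurement-quality patterns in digital consultation data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting facility-level measurement-quality patterns in digital consultation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Digital clinical decision support tools record every input a healthcare
worker enters during an outpatient paediatric consultation. When a
prompted measurement is skipped, entered without being taken, or taken
with poor technique, the recorded data leave statistical fingerprints:
excess "not feasible" entries, value distributions collapsed onto one or
a few heaped values, or implausible values that surface as extreme
growth z-scores. `signgaps` operationalises a facility-level screen for
these fingerprints on the numeric signs such tools collect —
temperature, MUAC, weight, height, heart rate, respiratory rate and
SpO2 — and the three derived growth indicators (MUAC-for-age,
weight-for-age, weight-for-height).

Because no gold standard for the "true" distribution of each sign
exists, every facility is compared against the pooled distribution over
all facilities. This is a pragmatic screen for the *most deviant*
facilities, not a test of absolute quality: a systematic error shared by
all facilities is invisible to it by construction.

## The data model

One consultation is one row: facility id, age in days, sex, a
respiratory-complaint flag, and per sign a status
(`measured` / `not_feasible` / `estimated` / `not_applicable`) plus a
value on the sign's recording grid when measured. Eligibility follows
the consultation tool's logic: MUAC is prompted only above 6 months;
heart rate, respiratory rate and SpO2 only for respiratory complaints.
Weight is never "not feasible" but may be "estimated"; estimated values
are treated as missing throughout, since only measured weights are
trustworthy.

## The synthetic cohort generator

Real consultation archives of this kind are not publicly deposited, so
the package ships a generator whose defaults emulate the study setting:
16 health centres of ~1,255 consultations each (~20,000 total), ages 1
day to 14 years with 60% of children under five (uniform within each
stratum), sex Bernoulli(0.5), and a respiratory main complaint in 35%
of visits.

Baseline value distributions are config-declared: truncated normals for
temperature (N(36.8, 0.5) on [35, 41] °C) and the vitals (heart rate
N(120, 20), respiratory rate N(35, 10), SpO2 N(97, 1.8) truncated at
100), and log-normal rides on smooth growth median curves for
anthropometry, with log-scale spreads matching the reference table's
coefficients of variation so that baseline z-scores are approximately
standard normal. Values are quantized to each sign's recording step
(0.1 °C, 0.1 cm, 0.1 kg, 1/min, 1%). Baseline not-feasible rates
(3–12% depending on the sign) are placeholders chosen to be plausible
for routine primary-care data entry; no published per-sign rates exist
to calibrate them against.

Four behaviours can be injected into any facility-sign pair, each
controlled by a single `intensity`:

* **skipper** — converts measured entries to "not feasible" so the
  missing fraction rises by `intensity`;
* **mono-repeater** — adds spike mass `intensity` on one target value;
* **multi-repeater** — adds spike mass `intensity` spread over 2–3
  target values;
* **wrongly evaluated** — with probability `intensity` replaces the
  value with an implausible one (anthropometry scaled to ~50–62% or
  ~160–185% of the child's value, which drives |z| well past 2; vitals
  and temperature pushed outside any plausible mean range).

Spike mass is *additive*: replacements are drawn from non-target
records with probability `intensity / (1 − current target mass)`, so
the targets' combined frequency rises by `intensity` in expectation and
the injected effect size lives on the same scale as the classifier's
excess-frequency statistic. Intensities beyond the attainable mass are
clipped with a warning. Each record draws one uniform deviate and is
affected iff it falls below the (derived) threshold, which makes every
injected distortion monotone in intensity at a fixed seed — a property
the test suite asserts.

What the generator does **not** emulate: age-structured vital-sign
norms (heart and respiratory rate in real children fall steeply with
age; here they are age-constant), seasonal and epidemic case mix,
worker-level heterogeneity within a facility, correlated behaviours
(real facilities often skip *and* heap), and naturally occurring digit
preference in the baseline. Passing calibration tests therefore shows
the detector recovers the behaviours *as modelled*, at realistic sample
sizes — not that it would perform identically on routine data, where
baseline heaping in particular would raise the pooled reference's modal
frequencies and make repeaters harder to single out.

## Growth z-scores

The consultation tool derives growth indicators from a child-growth
reference. The package uses the standard LMS parameterisation: with
power `L`, median `M` and coefficient of variation `S` at the child's
age (or height) and sex,

z = ((x/M)^L − 1) / (L·S),  or  log(x/M)/S when L = 0.

Parameters are linearly interpolated between grid rows. The bundled
table is a *synthetic* fixture built from smooth parametric median
curves (monthly ages 61 days–5 years; heights 45–120 cm in 0.5 cm
steps), not an official growth-standard release — adequate because
every analysis in the package is relative to this table, and the
generator uses the same curves, so baseline extreme-z fractions sit
near the theoretical ~4.6%. Z-scores are computed only for ages 2
months to 5 years, the validity window of under-five growth standards.

The tool displays z-scores as integers clamped to [−3, 3]. Whether the
original rounds or truncates is not documented, so the package declares
rounding half away from zero and retains the raw z alongside, letting
either convention be audited. All distribution comparisons use the raw
z; an extreme value is raw z < −2 or > 2.

## Summary statistics and their conventions

Per facility-sign pair: eligible count, measured count, missing
fraction (not feasible + estimated over eligible), modal value and
frequency, top-3 cumulative frequency, mean, median and IQR of measured
values; for z-indicators, the extreme-z fraction. The pooled reference
(`hc_id = "ALL"`) is the identical computation over all facilities
*including* the facility under test — deliberately not leave-one-out,
matching the screen's operational definition of "the average of all
facilities"; with 16 facilities the self-contribution dilutes an
injected effect by roughly 1/16.

Fixed conventions, each documented because results depend on them:
quantiles use linear interpolation between order statistics (type 7,
R's default); modal ties break to the smallest value; modal
frequencies are computed on the recording grid (a "most frequent
value" is only meaningful on the grid the tool accepts); a
facility-sign pair with fewer than 20 measured values is marked
insufficient and never classified, preventing spurious flags on tiny
cells. Both mean and median are computed and retained.

## The pattern classifier

Each facility-sign statistic is compared with the pooled reference and
the deviation mapped through three severity bands:

| criterion | mild | moderate | severe |
|---|---|---|---|
| excess missing fraction | 0.05–0.10 | 0.10–0.30 | > 0.30 |
| excess top-value frequency | 0.05–0.10 | 0.10–0.30 | > 0.30 |
| IQR shrinkage (ref − hc)/hc | 0.25–0.50 | 0.50–1.00 | > 1.00 |
| excess extreme-z fraction | 0.05–0.10 | 0.10–0.30 | > 0.30 |

"X% more frequent than the reference" is read as an **absolute
percentage-point difference** of fractions — the reading under which
the bands mix coherently with fraction-valued statistics; a
relative-ratio reading is available via `excess_scale = "relative"`.
IQR shrinkage ">100% smaller" cannot mean (ref − hc)/ref, which is
bounded by 100%; the adopted reading is shrinkage relative to the
facility's own IQR, so >100% means the facility's IQR is under half
the reference. A facility IQR of exactly zero against a positive
reference is treated as severe (infinite shrinkage). Frequency and IQR
criteria combine by OR with severity the maximum of the two.

Mono vs multi: the mono candidate uses excess modal frequency, the
multi candidate excess top-3 cumulative frequency. A spike on 2–3
values necessarily lifts the modal frequency a little, so precedence is
severity-aware: mono wins only when its band is at least as high as the
multi band; otherwise the stronger multi finding is kept. When only the
IQR criterion fires, the flag is typed mono (variance collapse around
one value). The wrongly-evaluated pattern uses excess extreme-z bands
for the indicators and, for temperature and vitals, an
implausible-mean route that yields a mild flag only (the config
exposes the plausibility ranges; they are screening defaults, not
published values).

Applicability: skipper is not assessed for temperature, weight and
z-indicators; repeaters not for weight, height and z-indicators;
wrongly-evaluated not for raw weight and height (their errors surface
through the z-scores). Temperature missingness is still *summarised*
(its missing fraction is on the summary row) but not *flagged* — the
pattern definitions exclude it, and the package follows the pattern
definitions.

A facility is **selected for observation** when at least two distinct
signs carry flags and at least one flag is moderate or severe.

## Calibration experiments

Two property-style experiments stand in for the original retrospective
table, which is not reproducible without the undeposited consultation
archive:

* **Null calibration** — 20 behaviour-free cohorts of 16 × 20,000
  consultations: the classifier should flag essentially no
  facility-sign pair (≥ 95% flag-free; observed 100%). Per-facility
  sampling noise at n = 20,000 is an order of magnitude below the mild
  band edges.
* **Injection recovery** — 50 runs of 16 × 2,000 consultations, each
  with one behaviour injected at a severity band-centre intensity
  (mild 0.075, moderate 0.20; the open-ended severe band uses 0.45),
  cycling over seven (sign, type) combinations × three bands. Recovery
  of the injected (sign, type) and of the severity band are the
  metrics. Repeater targets are the sign's most frequent baseline
  values: heaping lands on common round values, and top-k excess only
  responds when spike mass aligns with the recorded mode — spike mass
  spread far from the mode mostly *displaces* existing top values and
  is a genuinely harder detection problem at mild intensity.

Problem sizes (2,000–20,000 consultations per facility, 20–50 seeded
repeats) were chosen so each experiment pins the property it tests with
comfortable Monte-Carlo margin while a full run stays in the
few-minute range on a laptop. Mild-band injections on
small-denominator signs (the respiratory-complaint-gated vitals) sit
1–2 standard errors from the band edge and account for the few
expected misses; this is the detector's real operating floor, not an
artefact.

## Prospective observation analysis

The second arm of the workflow is descriptive: records of directly
observed consultations (one row per consultation × sign) carry a
performed flag, a sufficient/insufficient quality grade, multi-select
reason codes and, for respiratory rate, the measurement method (tap
app vs timer). Tallies report integer percentages (rounded half away
from zero, matching the printed presentation); reason prevalences are
per category and may sum past 100% because reasons are multi-select.

The packaged fixture is count-level (per-sign totals and per-reason
counts) and is expanded to record level in code, seeded: which record
carries which reason combination is arbitrary, since only marginal
counts are published — co-occurrence structure in the fixture is
synthetic and should not be analysed. Denominators for MUAC, heart
rate, SpO2 and respiratory rate are reconstructed from the published
skip percentages and the method split (and are labelled synthetic);
the three all-children signs use the published 188. The heart-rate and
SpO2 insufficiency tables are identical in the source material
(plausibly shared oximeter events); the fixture mirrors them as-is.

## Known limitations

* The pooled reference is contaminated by the facilities under test;
  a behaviour shared by many facilities shrinks every excess and can
  mask itself entirely.
* Thresholds are screening heuristics with no inferential guarantee;
  no significance testing is attempted, matching the descriptive
  intent.
* The severity of the implausible-mean route is not graded.
* Classification is at facility level; worker-level attribution is out
  of scope.
* The retrospective and prospective arms are not linked record-wise.
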