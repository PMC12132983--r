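# signgaps

Facility-level detection of clinical skill gaps from the numeric signs a
digital clinical decision support tool records during outpatient
paediatric consultations.

When healthcare workers skip a prompted measurement, enter a value
without measuring, or measure with poor technique, the recorded data
show characteristic fingerprints. `signgaps` screens for four of them,
per health centre and per sign, against the pooled distribution over all
centres (used as the reference in the absence of a gold standard):

| pattern | fingerprint | statistic |
|---|---|---|
| skipper | excess "not feasible" entries | missing fraction |
| mono-repeater | one heaped value, collapsed spread | modal frequency, IQR |
| multi-repeater | 2–3 heaped values, collapsed spread | top-3 frequency, IQR |
| wrongly evaluated | implausible values | extreme z-scores (\|z\| > 2), implausible mean |

Deviations map to **mild / moderate / severe** bands (excess fraction
0.05–0.10 / 0.10–0.30 / > 0.30; IQR shrinkage (ref − hc)/hc 0.25–0.50 /
0.50–1.00 / > 1.00). A centre is selected for on-site observation when
at least two signs carry flags and at least one is moderate or severe.

Growth indicators (MUAC-for-age, weight-for-age, weight-for-height) are
computed with the LMS transform `z = ((x/M)^L − 1)/(L·S)` from a bundled
synthetic reference table, for children aged 2 months to 5 years, and
clamped to the integer range [−3, 3] the consultation tool displays.

The package also covers the companion prospective arm: descriptive
tallies of directly observed assessments (performed/skipped,
sufficient/insufficient quality, multi-select reasons, and an app-vs-
timer comparison for respiratory rate), reproduced from a packaged
count fixture.

The intended audience is researchers and district health teams working
with consultation-level data from digital IMCI-style tools who want a
reproducible, threshold-based screen for which facilities to support
first.

## Worked example

The `analysis/` directory holds the numbered workflow. Step 1 simulates
16 health centres (~20,000 consultations) with ten known behaviours
injected at five centres; steps 2–4 attach z-scores, summarise, and
classify:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_zscores.R
Rscript analysis/03_summarize.R
Rscript analysis/04_classify.R
```

Step 4 prints:

```
flags: 11
 hc_id              sign      pattern_type severity
 HC-02        heart_rate           skipper moderate
 HC-02              spo2     mono_repeater moderate
 HC-03              muac           skipper moderate
 HC-03         resp_rate     mono_repeater moderate
 HC-05            height           skipper moderate
 HC-05    weight_for_age wrongly_evaluated moderate
 HC-05 weight_for_height wrongly_evaluated moderate
 HC-10       temperature     mono_repeater moderate
 HC-15        heart_rate     mono_repeater moderate
 HC-15         resp_rate           skipper   severe
 HC-15      muac_for_age wrongly_evaluated moderate
selected for observation: HC-02, HC-03, HC-05, HC-15
```

Every flag sits on an injected facility-sign pair (a corrupted weight
surfaces through both weight-based z-indicators, and a corrupted MUAC
through MUAC-for-age). HC-10's single flagged sign fails the two-sign
selection clause. The injected respiratory-rate spike on 34/35/36 at
HC-03 is read as a mono-repeater: its modal and top-3 excesses reach the
same band, and mono takes precedence at equal severity. Step 4 also
writes the facility-by-sign pattern matrix (`results/pattern_matrix.csv`,
cells like `"Skipper (moderate) - Mono (mild)"`) and diagnostic figures
(missingness bars, per-facility boxplots and densities, z-score
histograms).

Step 5 reproduces the prospective descriptive analysis from the
packaged fixture:

```sh
Rscript analysis/05_observe.R
```

```
 sign        n_total n_skipped n_sufficient n_insufficient pct_skipped ...
 temperature     188        14           48            126           7
 height          188        39           48            101          21
 ...
 method  n n_sufficient pct_sufficient
  rrate 39           29             74
  timer 39           18             46
```

i.e. temperature was measured with insufficient quality in 67% of
observed consultations, height skipped in 21% and insufficient in 54%,
and the tap-based respiratory-rate app produced sufficient measurements
almost twice as often as the full-minute timer (74% vs 46%).

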