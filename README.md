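# bedegress

Falls are a leading cause of injury among elderly in-patients, and about
half of them happen while getting into or out of bed — typically when a
patient tries to leave bed unnoticed. **bedegress** is a desk-scale R
implementation of an IoT bed-exit alerting system for clinical and
elderly-care settings: wearable accelerometer streams (a smartphone-class
50 Hz sensor, or a sparse passive-RFID sensor with RSSI) are communicated
to a central data sink over a low-latency TDMA superframe protocol,
classified there into *on-bed*, *off-bed* and *lying* activity, and turned
into alerts fast enough for staff to intervene — with an end-to-end delay
budget under a tenth of a second.

It is aimed at researchers in wearable-sensor activity recognition and
body-sensor networking who want a fully testable, data-free reference
implementation of the whole loop.

## What it implements

* **Superframe protocol** — beacon / channel-request registration /
  requested / periodic sections. Requests per frame follow a truncated
  Poisson law, P(i) ∝ αⁱe^{−α}/i! on 0..n. The averaged sensed-data delay
  is the per-request expectation

  `ds = E[Σ_r d(r)] / E[I]`, `d(r) = ⌊(r−1)/(m−p)⌋·T + (((r−1) mod (m−p)) + 1 − δ)·t`,

  computed exactly (`analytic_average_delay()`) and by a discrete-event
  Monte-Carlo simulator (`simulate_superframes()`), against a
  periodic-only baseline with mean TR/2 and worst case
  TR = ⌈n/p⌉·T (25 ms at the defaults). End-to-end totals add the
  processing delay σ and the feedback delay dc ∈ [t, ωt].
* **Feature extraction** — 151-sample (3.02 s) smartphone windows / 50
  received-sample RFID windows; per signal (x, y, z, SMV =
  √(ax²+ay²+az²)): 11 statistical descriptors, plus for the smartphone 11
  band energies of a 4-level periodized db10 discrete wavelet transform
  (E_abs per band D1..D4, A4; relative energies E_abs/E_total; E_total);
  axis correlations; RSSI descriptors for RFID — 91 features per
  smartphone window, 52 (or 53) per RFID window.
* **Classification** — random forest, RBF SVM, and class-weighted SVM with
  penalties N_max/N_i, stratified 5-fold cross-validation, per-class
  F = 2TP/(2TP+FP+FN)×100 and macro-averaged overall F. The six published
  cross-validation confusion matrices ship as a fixture and
  `verify_printed_tables()` recomputes all 24 published F cells from them.
* **Synthetic streams** — a phenomenological generator (gravity
  orientation per posture + gait oscillation + noise, motion-dependent
  RFID dropout, label-dependent RSSI) with default protocols matching the
  two modalities' class balances, so every stage is testable without any
  external dataset.
* **End-to-end pipeline** — change detection on SMV jumps, scheduling,
  sink-side classification, debounced alerts on sustained entry into
  on-bed/off-bed, and a full delay decomposition `total = ds + σ + dc`.

## Worked example

```r
library(bedegress)

# a labelled synthetic recording: ~77% off-bed, the rest on-bed / lying
stream <- generate_stream(default_protocol("smartphone"),
                          generator_params(seed = 42))

feats <- extract_features(stream, "smartphone")     # 79 windows x 91 features
cv <- cross_validate(feats, model_spec("wsvm", seed = 1), k = 5, seed = 1)
cv
#> <cv_result> wsvm, 5-fold, n = 79 windows
#> <performance_report>
#>   on_bed   F =  93.3 %
#>   off_bed  F =  99.2 %
#>   lying    F = 100.0 %
#>   overall  F =  97.5 % (macro average)

# communications + processing + feedback delay at 5 requests/frame,
# with a worst-case 76 ms processing budget
cfg <- superframe_config()
analytic_average_delay(cfg, delay_params(alpha = 5, sigma = 76e-3, config = cfg))
#> <delay_report [analytic]> alpha = 5, p = 5
#>   ds = 1.63 ms, sigma = 76 ms, dc = 1.2 ms, total = 78.83 ms
```

The cross-validation report says the weighted SVM recovers the three
activity classes nearly perfectly on the synthetic recording (macro F
97.5%, with the small on-bed minority the hardest class). The delay report
says that at an average of five channel requests per frame a sensor change
reaches the sink in 1.63 ms on average; even after adding the worst-case
processing budget and feedback delay, the total 78.8 ms stays under the
tenth-of-a-second alerting budget.

`tidy()` / `glance()` methods give tibble views of every report, and
`autoplot()` plots delay sweeps and confusion matrices. A thin CLI over
the same functions lives at `inst/cli/bedegress.R` (subcommands `synth`,
`features`, `classify`, `protocol`, `verify-tables`, `run`).

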