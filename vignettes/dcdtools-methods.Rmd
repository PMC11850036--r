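---
title: "Methods: time-to-death prediction and warm-ischemia quantification for DCD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-to-death prediction and warm-ischemia quantification for DCD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcdtools)
```

## The clinical problem

In donation after circulatory determination of death (DCD), organs can only
be recovered if the patient dies within roughly 30 minutes to 3 hours of the
withdrawal of life-sustaining measures (WLSM); longer agonal phases accrue
warm ischemic injury that makes organs unsuitable. Two decisions therefore
hinge on quantitative assessment: *before* WLSM, how likely is death within
each organ's eligibility window; and *after* WLSM, how much warm ischemia did
each organ actually accrue.

`dcdtools` implements both halves as a pipeline: beat-by-beat extraction of
R-peak intervals and arterial pressures from bedside waveforms, a 17-metric
heart-rate and blood-pressure variability panel, a calibrated random survival
forest producing monotone probabilities of death within 15-minute intervals
up to 4 hours, and an ischemia engine measuring time spent below
arterial-pressure and oxygen-saturation thresholds between WLSM and death.
The biological premise is that reduced beat-to-beat variability reflects
reduced physiological reserve and is associated with faster death after
withdrawal; the model additionally uses routine clinical features and the
attending physician's categorical prediction.

## The synthetic cohort: what it emulates and what it does not

No public waveform cohort of dying ICU patients exists, so the package ships
a seeded simulator (`sim_params()`, `simulate_cohort()`) whose cohorts carry
the variability-to-survival signal by construction. A single latent frailty
$f \sim \mathrm{LogNormal}(0, 0.6)$ per patient drives all three feature
families:

* **Beat-to-beat variability.** Pre-WLSM RR intervals follow an AR(1)
  process around 900 ms whose innovation SD is $35 \cdot f^{-0.8}$ ms —
  higher frailty, lower variability. Per-beat mean pressure and pulse
  pressure follow smooth AR(1) dynamics (coefficient 0.98, marginal SD
  $6 \cdot f^{-0.8}$ mm Hg) around MAP 83 / PP 45 mm Hg, with SBP and DBP
  derived from the conventional MAP = DBP + PP/3 identity.
* **Clinical severity.** Lactate, APACHE II, GCS, reflex loss and the other
  snapshot fields are noisy monotone functions of $\log f$, anchored to
  medians typical of adult DCD donor cohorts (APACHE II 24, GCS 4,
  FiO2 30%).
* **Time to death.** Post-WLSM time to circulatory arrest is Weibull with
  shape 1.1 and scale $70 / f^{1.2}$ minutes, giving a cohort median around
  40–50 minutes and roughly 70% mortality by two hours — deliberately in the
  range reported for attempted DCD.

The post-WLSM decline (`generate_post_wlsm_vitals()`) is deterministic given
the ground truth: MAP decays exponentially at rate $0.05 f$ per minute
toward an arrest plateau of 8 mm Hg, pulse pressure decays exponentially so
that it reaches exactly 5 mm Hg at the true time of death, and SpO2 falls
sigmoidally. Death is operationalised as the first instant from which pulse
pressure stays below 5 mm Hg for 5 continuous minutes — a computable
stand-in for sustained pulselessness plus the clinical no-touch observation
period. These trajectory shapes are stand-ins: the simulator makes no claim
to mechanistic cardiovascular realism, does not reproduce any real cohort's
joint distributions, and contains none of the measurement pathologies of
real bedside data (electrode artifact, line flushes, transducer drift).
Passing tests on simulated cohorts therefore demonstrate that the *pipeline*
recovers a signal of the stated form — not that the model is clinically
validated.

Waveform rendering places a fixed QRS template at each beat time on a 500 Hz
grid (beat times are aligned to that grid; the 2 ms quantisation is far below
physiological jitter) and scales an arterial pulse-wave template between each
beat's DBP and SBP at 125 Hz, with a flat systolic top and an exact return to
diastole so that per-beat extraction is well-posed. Full-rate rendering is on
by default for single patients and off for cohorts, where the beat-level
series is the working representation.

Reproducibility is strict: per-patient streams are derived deterministically
from the cohort seed, and identical `(params, seed)` reproduce a cohort
byte-for-byte, including rendered waveforms and serialized artifacts.

## Beat extraction

R peaks are detected with a Pan-Tompkins-style cascade (5–15 Hz zero-phase
Butterworth band-pass, derivative, squaring, 150 ms integration, adaptive
threshold at 0.4 times the running median of recent peak energies, 200 ms
refractory period), refined to the local ECG maximum within ±80 ms. Flatline
input yields an empty result with a warning rather than an error. Per-beat
pressures use the half-open convention: beat $i$ owns $[peak_i,
peak_{i+1})$, with SBP the maximum, DBP the minimum and MAP the time average
of ABP samples in that interval; beats whose interval leaves the record are
flagged missing, never silently dropped.

Artifact rules (configurable defaults): RR outside 250–3000 ms, successive
RR change above 30%, and pressure-order violations (SBP ≤ DBP or MAP outside
[DBP, SBP]) are flagged with reason codes; values are never modified, which
makes cleaning idempotent. A window with more than 50% artifacts raises a
quality error advising it be discarded.

## The variability panel

Metrics are computed on non-overlapping windows of exactly 750 accepted
beats spanning at most 60 minutes (longer spans are rejected), separately
for the RR-interval, systolic and diastolic (and optionally mean) pressure
series. The stride choice — non-overlapping — avoids double-counting
evidence; it is an assumption, since only the window length is conventional.
The 17 metrics span the standard time-domain, frequency-domain and nonlinear
families: SDNN, RMSSD, a pNN-style fraction (50 ms threshold for RR, 2 mm Hg
for pressures), coefficient of variation, Poincaré SD1/SD2 and their ratio,
DFA alpha1/alpha2/AUC, grid count, sample entropy, multiscale-entropy AUC
(scales 1–5), and Lomb-Scargle LF/HF/total band powers with the LF/HF ratio.

Three definitions deserve notes:

* **Poincaré SD1/SD2** are the SDs of $(x_{i+1} \mp x_i)/\sqrt{2}$ — the
  dispersion perpendicular to and along the identity line of the lag-1
  embedding. The identity $SD1^2 + SD2^2 = \mathrm{var}(x_{2:n}) +
  \mathrm{var}(x_{1:n-1})$ is asserted in tests.
* **DFA** integrates the mean-centred series, detrends linearly in
  non-overlapping boxes (forward and backward), and fits
  $\log F(n)$ vs $\log n$ over boxes 4–16 (alpha1) and 17–64 (alpha2), with
  the AUC the trapezoidal area under the whole log-log curve. Plain DFA1 is
  biased upward at small boxes: for white noise the exact expectation is
  $E[F^2(n)] = \sigma^2 (n^2-4)/(15n)$, so the local slope over boxes 4–16
  is ≈ 0.59 rather than 0.5. We therefore divide $F(n)$ by
  $\sqrt{1-4/n^2}$ — the exact correction normalised to preserve the
  asymptotic $\sqrt{n/15}$ law — after which white noise scales at 0.500 and
  an integrated random walk at ≈ 1.41 over the conventional box range. This
  "modified DFA" choice keeps the standard short-scale boxes interpretable.
* **Grid count** bins consecutive pairs on a 32 × 32 grid over a *fixed*
  physiological range (RR 250–3000 ms, pressures 0–250 mm Hg) and reports
  the fraction of visited pixels, making values comparable across windows;
  a data-range fallback exists for exploratory use, with a constant series
  defined to occupy a single pixel. Clinical displays sometimes show this
  occupancy as a percentage; the package returns the fraction.

Band powers use a classical Lomb-Scargle periodogram evaluated on the uneven
beat times (0.003–0.4 Hz, 256 frequencies), scaled so the full-band integral
matches the series variance; LF is 0.04–0.15 Hz and HF 0.15–0.4 Hz. Sample
entropy uses $m = 2$, $r = 0.2\,\mathrm{SD}$, with the tolerance fixed from
the scale-1 SD across multiscale-entropy scales. Degenerate inputs (constant
series) yield flagged `NA` metrics rather than errors.

## Prediction

Four model variants mirror the available information blocks: variability
only, clinical only, physician only, and combined. Features are fixed-order
numeric vectors: the per-metric *median over the most recent hour of
windows* for each source series (freshest data, one number per metric), the
16 clinical fields with booleans as 0/1, and the physician's category
encoded as its ordinal midpoint in minutes (30, 60, 120, 180, 360, 480) plus
confidence as 1–3.

The forest is a ranger random survival forest (1000 trees by default,
$\sqrt{p}$ candidate features per split, minimum node size 5, single
thread for determinism) on times right-censored at 240 minutes — the
4-hour prediction cap. Raw event probabilities $1 - S(h)$ at the 16
horizons are recalibrated per horizon by isotonic regression fitted on the
forest's out-of-bag predictions against the observed binary outcomes;
isotonic regression is monotone, distribution-free and standard for
recalibrating survival probabilities. Because independently fitted
per-horizon maps need not be jointly monotone, each patient's 16-horizon
vector is finally projected onto the monotone cone by pool-adjacent-violators
(the least-squares monotone projection) and clipped to [0, 1]. An earlier
design used a running maximum here; that was discarded because a running
maximum can only raise probabilities and therefore systematically inflates
the early horizons, whereas the L2 projection redistributes violations
symmetrically. The structural invariants (probabilities in [0, 1], monotone
across horizons) are asserted on every prediction. Horizons at or below the censoring cap have fully observed
binary outcomes, so no inverse-censoring weights are needed. Missing feature
values are median-imputed with training medians, with a missingness
indicator added for any feature that was ever missing in training.

Evaluation utilities compute Harrell's concordance (via
`survival::concordance`), calibration-in-the-large (mean predicted
probability vs observed frequency with exact binomial CIs) at 30/60/120
minutes, per-horizon serial stability (the range of probabilities across a
patient's repeated assessments, summarised as the cohort median of each
patient's maximum change), and the physician's categorical accuracy (a
category is correct at horizon $h$ when "predicted death by $h$" matches
"died by $h$").

The test suite checks signal recovery on a documented cohort of 600
simulated donors (400 train / 200 held out, fixed seeds): held-out
concordance of the combined model above 0.65 and above the physician-only
model; calibration-in-the-large within ±0.05 at 30/60/120 minutes; and
chance-level concordance (0.45–0.55 over 20 replicates) when features are
replaced by pure noise — the latter guarding against any leakage between the
simulator's ground truth and the feature path. Calibration-in-the-large is a
population property whose single-cohort estimate at n = 200 carries binomial
noise of about ±0.035, so it is measured as the mean absolute gap over three
seeded cohort replicates — the same replication logic the scaling-exponent
and noise-control checks use — with the ±0.05 band applied to that mean. Serial assessments (2–4 per
patient, fresh beat-series realisations under the same frailty) verify that
the combined model is at least as stable over time as the variability-only
model, since its constant clinical and physician blocks dilute sampling
noise in the variability block. Problem sizes (600 + 60 patients, 500-tree
forests in tests, 60-second detector records) were chosen as the smallest
cohorts at which these properties are comfortably away from their decision
boundaries.

## Ischemia quantification

`time_below_thresholds()` treats a vitals trajectory as piecewise linear and
returns the Lebesgue measure of $\{t: v(t) < c\}$ per cutoff, interpolating
at crossings so the result is independent of sampling rate; sampling gaps
longer than 30 s are excluded from the measure and reported. Interval
boundaries are interpolated too, which makes durations additive over
adjacent sub-intervals. Nested-cutoff monotonicity (less time below a lower
cutoff) holds by construction and is asserted on all outputs. Default
cutoffs (MAP 60/50/40/30, SBP 80/60/50, SpO2 80/70/60) bracket common
functional-warm-ischemia definitions but are configuration, not clinical
authority; the same holds for the organ windows (lungs/liver/pancreas 60
min, kidneys 120 min, all within the conventional 30 min–3 h envelope).
`ischemia_summary()` combines the death-time rule, per-cutoff durations,
first sustained crossing times (0.5 min sustain), and organ-window flags;
missing SpO2 produces a pressure-only summary flagged incomplete, and a
record with no observed arrest is summarised over its full span with a
truncation flag.

## Reports and CLI

Reports are data-first: one JSON payload per report, identical for every
audience, with an MD5 content hash linking every rendered number to its
pipeline artifact; the ICU and transplant renderings differ only in section
order and an organ-focused appendix, so both teams see the same numbers. The
prediction block leads, headlined by the 30/60/120-minute triple, which is a
projection of the full 16-horizon vector. Payloads validate against JSON
schemas shipped under `inst/schema/` (a pragmatic structural subset of JSON
Schema implemented in-package). The `inst/cli/dcdtools` Rscript exposes the
pipeline (`simulate`, `extract`, `variability`, `train`, `predict`,
`ischemia`, `report`) with option precedence CLI flag > YAML config >
default and timestamped logs on stderr; `cli_main()` is the testable
surface.

## Numerical and design choices, and limitations

* Waveform interchange uses a documented long-format CSV dialect
  (`time_s,channel,value` with `# key=value` header lines); WFDB input is
  recognised but unsupported in this build and reported as such.
* The beat-interval convention is half-open $[peak_i, peak_{i+1})$ —
  partitions time without double counting.
* The artifact thresholds, grid ranges, DFA boxes, spectral bands, ischemia
  cutoffs and organ windows are all exposed configuration with the defaults
  stated above; none is claimed to replicate the original clinical tool's
  unpublished settings, and the identity of the original 17-metric panel is
  likewise not public — the panel here spans the same metric families and
  includes the four publicly defined members (Poincaré SD2, DFA alpha1, DFA
  AUC, grid count).
* The simulated physician is future-blind by design: their category is the
  implied median survival of a noisy assessment of the patient's state (the
  latent frailty), never the realized survival time, and their stated
  confidence tracks the assessment error only loosely. The assessment noise
  default (SD 0.7 on the log-frailty scale) was chosen so that simulated
  categorical accuracy lands in the 0.6–0.75 range reported for clinicians
  predicting death within 30 min–6 h. An earlier construction that added
  ordinal noise to the *true* category was discarded: it hands the simulated
  physician oracle access to the realized outcome, and with
  confidence encoding the error magnitude it made the physician-only model
  unrealistically strong.
* All probabilities are per-horizon cumulative risks from a single-event
  model; competing risks, treatment changes after WLSM, and inter-rater
  physician variability are out of scope.
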