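---
title: "Thalamic IED analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thalamic IED analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalied)
```

## Scope and data model

`thalied` analyses multichannel recordings taken during the externalized
window after bilateral ANT-DBS implantation: scalp EEG (modified 10-20
subset) and two 4-contact thalamic leads, sampled at a common rate
(2048 Hz in the clinical setting this emulates). A `recording` holds the
samples-by-channels matrix in microvolts, a channel table, and
sleep/awake/seizure annotations. Time is seconds from record start,
samples are 0-based externally, intervals are half-open `[start, end)`.
Contact 0 is the deepest contact of each lead.

The pipeline is: select 20 analysable minutes per vigilance state (kept at
least 2 h from seizures), detect and classify IEDs per site, compute
IED-triggered average potentials between scalp and thalamus, classify each
of the 8 per-patient conditions, assign contacts to thalamic regions, and
associate everything with 1-year seizure outcome.

## The synthetic world

The generator states the conditions the analysis assumes; its defaults are
fixed once and are not tuned against test outcomes.

* **Background**: Gaussian 1/f^α noise, default α = 1.5 and SD 10 µV —
  a standard stylized EEG background; sleep segments add a 0.5–2 Hz
  three-sinusoid mixture (amplitude = the noise SD) as a stand-in for
  slow-wave activity. No head-model forward projection is attempted.
* **Events**: spike-and-slow-wave templates. The fast lobe is a raised
  cosine whose FWHM is the stated fast duration (default 30 ms, 80 µV
  thalamic / 60 µV scalp); the slow wave is an opposite-going raised
  cosine (default 150 ms, 40 µV / 30 µV). Amplitudes are free parameters
  of the stated world: no amplitude statistics are available for thalamic
  IEDs. A shallow recovery lobe (FWHM twice the slow duration) balances
  the area so each rendered template is exactly zero-mean over its
  support; without it the zero-mean correction becomes a DC pedestal under
  the complex and biases width measurements.
* **Rates**: per site and state, Poisson processes thinned to ≥ 1 s
  same-site separation so epochs do not overlap trigger-adjacent events.
  Thalamic defaults are the observed medians (0.33/min sleep, 0.13/min
  awake). The observed awake scalp median is 0/min; a zero default would
  make every awake scalp-triggered condition degenerate, so the default is
  a small representative 0.10/min (a majority of patients do show awake
  scalp IEDs). Sleep scalp default is 0.26/min.
* **Coupling**: each scalp event is echoed in the same-side thalamus with
  probability `coupling_probability` (default 0.55, matching the follower
  fraction), at a truncated-normal lag (defaults mean 51 ms, SD 30 ms,
  bounds 2–180 ms — only the mean and range are reported in the source
  setting, so the SD is a package choice). Coupled echoes are drawn out of
  the thalamic rate budget where possible: the total thalamic count stays
  Poisson at the configured rate as long as expected echoes do not exceed
  it. The probability may be set per side, which the cohort driver uses to
  silence sides without thalamic IEDs.
* **Spatial spread**: one stable generator per side — the scalp focus
  channel and the thalamic peak contact are drawn once per recording, not
  per event. Real IED generators are spatially stable; per-event
  re-drawing would partially cancel the triggered averages and make peak
  contacts meaningless. Scalp events project to the focus channel plus
  its chain neighbours at half amplitude; thalamic spikes to the peak
  contact plus one adjacent contact at 0.4; sharp transients are inserted
  common-mode on all four contacts (no phase reversal by construction).
* **RNG**: one stream keyed by `(seed, patient id)`, so any patient can be
  regenerated independently and byte-identically (EDF headers carry a
  fixed start date for this reason).

What a green test on this world establishes: the detector, averaging, and
bookkeeping recover known ground truth under stylized but fair conditions.
What it does not establish: performance on real recordings with artifacts,
electrode drift, non-Gaussian backgrounds, or morphologies far from the
template family.

## Detection: operationalizing visual criteria

The visual definitions ("prominent amplitude", "outstanding
graphoelement") are not quantified in the source setting; the package
makes each one an explicit parameter and reports the defaults with
results.

* **Prominence**: a candidate is a local extremum whose detrended
  amplitude exceeds `prominence_threshold` (default 6) times the robust
  background SD (1.4826 × MAD over 60 s blocks). Two detrending scales
  matter: amplitude is measured after a 0.4 s running-median detrend
  (which passes < 100 ms transients untouched), but the background SD is
  estimated on a 1.6 s-detrended trace — the signal as a reviewer sees it
  at a ~0.5 Hz display high-pass. Judging prominence against the heavily
  detrended residue alone would flag ordinary noise maxima.
* **Fast duration**: full width at half-prominence. The reference level
  is the local foot of the peak (the larger of the two flanking medians,
  floored at the pre-event baseline), measured on the raw trace: the
  running-median detrend distorts the complex when it fills most of the
  median window.
* **Slow wave**: opposite-polarity area in the 80–400 ms post-peak window
  ≥ 0.25 × the fast-component area, both against the pre-event baseline.
* **Phase reversal**: opposite-signed deflections exceeding half the
  prominence threshold on two adjacent bipolar channels within ±20 ms.
* **Classification**: spike iff fast < 50 ms AND slow wave AND phase
  reversal AND monopolar prominence; any outstanding transient failing a
  criterion is a sharp transient regardless of duration; `reject` only
  for candidates prominent in neither montage. Scalp events are detected
  on the bipolar scalp montage only and are not class-refined.
* **Merging and absorption**: suprathreshold deflections within 200 ms
  merge across channels (strongest wins); thalamic candidates are pooled
  from bipolar and monopolar views because a purely common-mode event is
  invisible in bipolar. A candidate within 1 s of a ≥ 5× more prominent
  one is absorbed — the slow-wave and recovery phases of a complex are
  not separate events.

## Triggered averaging and conditions

Epochs span ±500 ms with the IED peak at 0 ms; triggers within 500 ms of
a record edge are dropped and counted. The IED-TP peak is the
maximal-absolute extremum exceeding 4 × the baseline SD of the average
(SD over −500…−250 ms); below that, the condition is "no connection".
Latencies inside ±2 ms (the smallest observed follower lag) are
`not_evaluable` rather than forced into a category: at 0 ms the sign is
noise. The target channel per direction is the target site's bipolar
channel with the largest absolute peak; channel selection is not specified
in the source setting, so this is a package choice. Each of the 8
conditions is an independent unit; disagreements between the two
directions of one (side, state) are reported as they are.

## Anatomy and bookkeeping

Imaging-based localization is replaced by coordinates plus an axis-aligned
box atlas (closed bounds; boundary points belong to the box; boxes must
not overlap). A lead hits iff ≥ 1 contact lies in an ANT subregion; MD
contacts do not count toward a hit. Focus-side hit means the dominant
side's lead hit, or a bilateral hit when the focus has no lateral
dominance.

Region occurrence counts one unit per (patient, side, region): multiple
contacts in the same region of one patient count once, and the left and
right instances of a nucleus are distinct sampled regions. The
reference cohort's printed aggregates are mutually consistent only under
this side-aware reading (a per-patient reading would require more
spike-positive ANT-V patients than patients with any ANT spikes).

## Outcome statistics

Seizure reduction is `100 × (pre − post)/pre` between the 3-month
pre-implant count and the 3 months before 1-year follow-up; responders
have strictly more than 50% reduction, so exactly 50.0% is a
non-responder (the reference cohort contains such a boundary patient).
Percentages print as half-up integers (55/120 → 46%). Odds ratios are
cross-product ratios; zero denominators give `Inf` unless the
Haldane–Anscombe correction is requested. Fisher exact, Wilcoxon, and t
tests delegate to R's `stats` implementations; the test suite checks them
against independent enumeration oracles (full hypergeometric table
enumeration, 2^n sign-flip enumeration) rather than re-implementing them.

## The reference cohort fixture

`paper15_cohort()` is a synthetic 15-patient world stated as raw inputs:
contact coordinates, region-level IED presence, per-condition IED-TP
latencies, seizure counts, and focus laterality. It was constructed so
that *all* cohort-level aggregates hold simultaneously — 6/15 responders;
9 bilateral and 6 unilateral hits (24/30 leads, 55/120 ANT contacts, 21 MD
contacts in 10 patients, 41 sampled regions); 11 focus-side hits with 5
responders; 7 focus-side-spike-TIED patients with 5 responders; ANT spikes
in all responders and 4/9 non-responders; 13 patients with any thalamic
IED, 7 of them bilateral; 60 evaluable conditions splitting 33/3/24 into
follower/preceder/no-connection with follower lags spanning 2–180 ms and
mean exactly 51 ms. `cohort_report()` recomputes every aggregate from
these raw inputs through the package's own functions. One detail has no
exact solution: three preceder lags within the reported 15–25 ms range
cannot average exactly 18 ms; the fixture uses {15, 15, 25}, whose mean
prints as 18.

## Numerical choices and degenerate inputs

* Ties in the peak-contact search break toward the deepest contact.
* A zero pre-implant seizure count makes seizure reduction undefined and
  raises an error rather than returning a silent `Inf`.
* Identical paired samples return p = 1 from the signed-rank wrapper
  (R's `wilcox.test` errors after dropping all zero differences).
* Empty subgroups error in `response_rate`; empty segments return empty
  candidate lists; zero usable triggers error in epoch extraction.
* Monte-Carlo test sizes are scaled down (512 Hz or less, minutes-long
  segments) to keep the suite inside a CPU budget; the tested properties
  — detection sensitivity/precision, false-positive rates, 1/√n averaging,
  lag recovery on a 2–180 ms grid — are rate- and scale-invariant.

## Known limitations

Artifact handling is limited to the robust background estimate (an
amplitude mask is the only provision for real data); REM staging,
imaging-based localization, HFO analysis, and seizure detection are out of
scope. The classifier's slow-wave and phase-reversal operationalizations
are surrogates for visual judgement and should be reported alongside any
result that depends on them.
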