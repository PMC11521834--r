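---
title: "High-gamma language mapping on SEEG: montages, percent change, and the synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-gamma language mapping on SEEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Stereo-EEG (SEEG) samples the brain with depth electrodes: shafts of 6 or
10 linearly spaced contacts (10 mm and 5 mm centre-to-centre) that traverse
gray matter, white matter, CSF and, at their superficial ends, tissue
outside the brain. Event-related increases of high-gamma (60–140 Hz)
amplitude are a standard surrogate of local cortical activation and the
basis of passive language mapping. Two artifact families threaten the
interpretation of SEEG high-gamma maps:

* **far-field potentials** — volume-conducted gray-matter activity recorded
  at white-matter contacts, which makes electrically silent tissue look
  active;
* **facial EMG** — orofacial muscle activity during overt speech, which
  contaminates contacts near or outside the skull during the response
  period of a naming task.

Both artifacts are spatially smooth: nearby contacts receive nearly the
same contribution. Local re-referencing (bipolar: contact minus its deeper
neighbour; Laplacian: contact minus the mean of both shaft neighbours)
therefore cancels them, while a common average reference (CAR) does not.
This package implements the full analysis that quantifies these effects —
montage operators, Morlet high-gamma percent change, phase-wise maximum
features, mixed-model contrasts — together with a synthetic SEEG generator
that reproduces the statistical structure the analysis assumes, so every
stage is testable without patient data.

## The pipeline

### Montages as explicit linear operators

Each montage is a derived-by-recorded weight matrix (`build_car()`,
`build_bipolar()`, `build_laplacian()`), auditable via
`write_montage_tsv()`. Conventions:

* The CAR average is computed over channels with no exclusion flag whose
  category is neither `outside` nor `csf`; irritative-zone channels are
  excluded from the *average* but retained in the *analysis* — the two
  sets are deliberately distinct in the code. The subtraction is applied
  to every analyzed channel, including extracranial ones.
* Bipolar derivations inherit the identity and anatomical category of the
  superficial (non-reference) contact; Laplacian derivations inherit the
  centre contact. Category labels for derived channels are a convention,
  not a measurement; this one keeps each derived channel attached to the
  contact whose activity it is meant to represent.
* Adjacency is strict on `contact_index` within a shaft: an excluded
  intermediate contact breaks a pair rather than letting the montage
  bridge across it. Shaft ends yield no Laplacian channel, and the deepest
  contact yields no bipolar channel.

Every bipolar/Laplacian row sums to zero, and CAR rows over averaged
channels sum to zero, so each scheme annihilates a component common to its
referenced set — the property the whole montage comparison rests on.

### Epoching and edge control

Trials are cut over the half-open window [−0.7 s, +5.1 s) around each
stimulus onset, sample-exactly. The *analyzed* window is [−0.5, +5.0] s.
The padding (200 ms before, 100 ms after) exists because a wavelet
estimate within half a wavelet of a data edge is contaminated: the longest
kernel (60 Hz, 7 cycles, envelope SD `7/(2*pi*60)` ≈ 18.6 ms, truncated at
4 SD) spans ±90 samples ≈ ±75 ms, so every analyzed sample keeps a full
kernel inside real data. A reported epoch display window of −200 ms cannot
contain a −500 to −200 ms baseline; we resolve this by extracting the
larger window and treating −200 ms as a display convention. Trials whose
window does not fit in the recording are dropped with a warning, never
silently, and trial ids are stable under dropping.

### Morlet amplitude and percent change

For each of the 41 frequency bins (60, 62, …, 140 Hz) the epoch is
convolved with a complex Morlet wavelet of 7 cycles (Gaussian envelope SD
`n_cycles/(2*pi*f)`); "amplitude" is the magnitude of the complex
coefficient, not power. The gain `2/(fs*sigma*sqrt(2*pi))` makes a
unit-amplitude sinusoid yield magnitude 1 at its bin, flat across
frequency; the unit tests verify the implementation against a brute-force
direct-convolution oracle to well under 2%.

Computationally, the convolution is frequency-domain multiplication on the
zero-padded epoch, and the 10-ms output grid is obtained by spectral
folding: summing the 12 aliased segments of the product spectrum and
taking a short inverse FFT equals sampling the full convolution every 12th
sample exactly. This keeps the full pipeline (tens of derived channels ×
trials × 41 bins) at about 10 ms per epoch without approximation.

Percent change is per trial and per frequency bin:
`100*(amp - B)/B` with `B` that trial's mean baseline amplitude in
[−0.5, −0.2) s, then averaged across the 41 bins into one broadband
series. Normalising per bin *before* averaging compensates the 1/f
amplitude slope so all bins contribute comparably. The baseline mean is
taken on a 5-ms grid that interleaves the 10-ms output steps; with a
baseline estimated only on the output grid itself, the baseline-window
percent change would be zero by construction and null checks would be
vacuous. Two small but real statistical properties follow from the ratio
form and are worth knowing:

* a finite baseline estimate gives `E[amp/B]` slightly above 1 (Jensen's
  inequality), so even task-free data shows a small positive percent
  change, about +2% at these window sizes;
* the phase-wise *maximum* of a noisy series is positively biased, so
  null features sit near +100% rather than 0 — the montage contrasts are
  differences between montages and are unaffected.

### Features and models

The dependent variable is the maximum broadband percent change per
channel, trial and phase: stimulus 0–1.8 s (closed right edge: a 10-ms
step centred exactly at 1.8 s is stimulus phase) and response (1.8, 5.0] s.
Montage comparisons are summarised two ways: median reductions
(`median_reduction()`, `100*(median_CAR - median_other)/median_CAR` per
stratum) and linear mixed models per anatomical category × phase
(`fit_mixed()`): `max_pc ~ montage + condition + (1 | patient)`, REML,
reference levels CAR and overt. Separate models per phase mirror how such
results are tabulated. Choices that were genuinely open:

* **Degrees of freedom**: residual (observations minus fixed effects) by
  default — consistent with the very large denominator df that
  trial-level SEEG fits report — with Satterthwaite available via
  `df_method = "satterthwaite"`.
* **FDR family**: all estimable fixed-effect contrasts (BP, LAP, covert)
  across the up-to-8 strata of one run form a single Benjamini–Hochberg
  family at 0.05; intercepts are excluded.
* **Degenerate designs degrade explicitly**: one patient → OLS (the
  random intercept is unidentifiable); singular mixed fit → refit as
  fixed-effects, with a message. Trials are independent observations
  within patient; no channel-level random effect is modelled because the
  feature is defined per trial.

## The synthetic test bed

`simulate_run()` generates referential recordings with exactly the
structure the analysis assumes, plus a ground-truth ledger (mixing
weights, envelopes, optionally raw potentials) for oracle tests.

* **Geometry**: collinear shafts at the commercial spacings; contact 1 is
  the deepest; categories are per-shaft patterns.
* **Gray sources**: band-limited (60–140 Hz) Gaussian noise — the weakest
  waveform assumption consistent with "high-gamma modulation" — with a
  trapezoidal trial envelope: baseline amplitude 5 µV RMS, ×2.5 during
  the stimulus phase, ×2.0 during the response phase. The default
  scenarios place an independent source at *every* gray contact: cortex
  is locally active wherever it is sampled. This matters — with sources
  at isolated contacts, a bipolar derivation against a silent gray
  neighbour inherits the neighbour's source and gray-matter medians would
  differ across montages for a purely geometric reason real cortex does
  not have.
* **Volume conduction**: instantaneous inverse-power amplitude decay,
  weight `(d0/(d+d0))^p` with p = 2, d0 = 1 mm, normalised to 1 at the
  source's own contact (quasi-static field spread; no propagation delay).
* **EMG**: broadband 20–300 Hz noise active only in the response phase,
  injected at `outside`-category contacts with inverse-distance decay
  from a locus just beyond one shaft's superficial end (the anchor bolt
  sits in the temporal muscle). Amplitudes are at-the-muscle RMS: 300 µV
  overt, 75 µV covert. Locating the locus near one shaft keeps a genuine
  spatial gradient across adjacent extracranial contacts, which is what
  leaves bipolar/Laplacian residuals small but non-zero.
* **Background**: independent 1/f noise per contact, parameterised by its
  RMS *inside* the analysis band (1.5 µV) because that is the quantity
  baseline high-gamma amplitude is made of (total broadband RMS would
  depend on recording length through the lowest resolved frequency).
* **Reference**: every channel is its contact's potential minus the
  potential of one shared white-matter contact. The reference channel
  itself is flat and is flagged artifactual in the generated channel
  table, exactly as it would be excluded in a real referential SEEG
  data set. Overt and covert runs with one seed share all waveforms and
  differ only in EMG amplitude at outside contacts.

No amplitude scale for task-related augmentation is established in the
literature at this level of abstraction; the numbers above are deliberate,
fixed package defaults, and since percent change is invariant to scaling a
whole channel, only their ratios matter. Patient heterogeneity in
`simulate_cohort()` multiplies the task effects by a lognormal factor
(SD 0.2 on the log scale), which is what makes the patient random
intercept real.

What the generator does *not* emulate: biophysical forward models (no
head geometry), ocular/saccadic artifacts, line noise, non-stationary
background, electrode drift, or genuine linguistic response-latency
variability. Passing tests therefore demonstrate that the pipeline
recovers the modelled structure — spatially smooth far fields, phase- and
condition-locked EMG, locally maintained gray-matter signal — not that it
is robust to everything real recordings contain.

## Problem sizes used by the checks

The montage-direction checks run the full pipeline on the two-shaft
scenario with 50 trials per condition; mixed-model coverage uses 200
simulated cohorts of 5 patients × 40 trials; the null pipeline runs 100
independent two-patient replicates of 5 trials each. These sizes give the
medians and rates enough precision for strict directional assertions while
keeping a complete run of the test suite and acceptance script in the
ten-minute range on one core.

## Known limitations

* EDF support is read-only and requires a uniform sampling rate across
  signals.
* The spatial snapshot is an abstract scatter of contact coordinates; a
  brain mesh is out of scope (a user-supplied background could be layered
  onto the returned data).
* Bipolar category labelling is a convention (superficial contact); with
  categories alternating contact-by-contact along a shaft, any convention
  misattributes some derived channels.
* The mixed model treats trials as exchangeable within patient; serial
  correlation across trials is not modelled.
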