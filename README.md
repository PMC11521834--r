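# seeghg — high-gamma language mapping on SEEG depth electrodes

Passive language mapping with stereo-EEG (SEEG) localises cortex by
event-related increases of high-gamma (60–140 Hz) amplitude during an
auditory naming task. Depth-electrode recordings, however, are contaminated
by **far-field potentials** (volume-conducted gray-matter activity recorded
in white matter) and, when the patient answers aloud, by **facial EMG** at
contacts near or outside the skull. Both artifacts are spatially smooth, so
the choice of montage decides how much of them survives: a common average
reference (CAR) leaves them in, while bipolar and Laplacian derivations —
being differences of adjacent contacts — cancel them and keep the local
cortical signal.

`seeghg` is the full analysis for quantifying this, aimed at intracranial
EEG researchers:

* the three montages as explicit, auditable linear operators
  (derived × recorded weight matrices);
* complex Morlet wavelet amplitude (2-Hz bins, 7 cycles, 10-ms steps) with
  per-trial baseline percent change
  `100·(A_f(t) − B_f)/B_f` averaged over the 41 bins,
  baseline −500 to −200 ms;
* phase-wise maximum features: `max_pc` per channel × trial in the stimulus
  (0–1.8 s) and response (1.81–5 s) phases;
* montage summaries: median reductions vs CAR, and linear mixed models
  `max_pc ~ montage + condition + (1 | patient)` per anatomical compartment
  (deep white matter, shallow white matter, gray matter, outside the brain)
  and phase, with Benjamini–Hochberg FDR at 0.05;
* a synthetic SEEG generator (shaft geometry, inverse-power volume
  conduction, response-phase EMG, 1/f background, shared white-matter
  reference) with a ground-truth ledger, so every stage has an oracle.

The methods vignette (`vignettes/highgamma-montage-mapping.Rmd`) documents
the model, the numerical choices and what the simulator does and does not
emulate.

## Worked example

Simulate a two-shaft referential SEEG run (20 trials, overt naming) and ask
how much each montage attenuates the response-phase deflections per
compartment:

```r
library(seeghg)

run   <- run_config(n_trials = 20, first_onset_s = 2, rng_seed = 7L)
sim   <- scenario_shaft_pair(seed = 7L)
overt <- simulate_run(sim, run, "overt")
overt$recording
#> <seeg_recording> 20 channels x 237120 samples @ 1200 Hz (197.6 s), montage: original

pl <- hg_pipeline(overt$recording, overt$channels, overt$events, run)
for (cat in c("outside", "deep_wm", "gray")) {
  for (m in c("bipolar", "laplacian")) {
    cat(sprintf("%-8s %-9s median reduction vs CAR: %5.1f%%\n", cat, m,
        median_reduction(pl$features, cat, "response", "overt",
                         montage_b = m)))
  }
}
#> outside  bipolar   median reduction vs CAR:  60.6%
#> outside  laplacian median reduction vs CAR:  63.1%
#> deep_wm  bipolar   median reduction vs CAR:  43.1%
#> deep_wm  laplacian median reduction vs CAR:  35.0%
#> gray     bipolar   median reduction vs CAR:   1.2%
#> gray     laplacian median reduction vs CAR:  -0.6%
```

Reading: relative to CAR, bipolar and Laplacian shrink the response-phase
maxima by ~60% at extracranial contacts (where the overt-speech EMG lives)
and by ~35–43% in deep white matter (volume-conducted far field), while
gray-matter maxima change by about a percent — local cortical activity is
maintained. `run_contrasts(features)` turns the same features into
mixed-model estimate/SE/t/p/CI tables per compartment × phase with FDR
flags.

## The analysis workflow

The `analysis/` scripts run the whole study on the larger eight-shaft
scenario and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # synthetic cohort data -> results/sim/
Rscript analysis/02_map_highgamma.R     # montages, percent change, features, figures
Rscript analysis/03_montage_contrasts.R # median reductions + mixed-model tables
```

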