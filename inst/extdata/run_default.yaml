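band_lo: 60.0
band_hi: 140.0
freq_step: 2.0
n_cycles: 7.0
tf_step_ms: 10.0
baseline_window_s:
- -0.5
- -0.2
stimulus_phase_s:
- 0.0
- 1.8
response_phase_s:
- 1.81
- 5.0
analysis_window_s:
- -0.5
- 5.0
epoch_window_s:
- -0.7
- 5.1
n_trials: 20
isi_s: 10.0
stim_dur_s: 1.8
first_onset_s: 2.0
rng_seed: 42
df_method: residual
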