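shafts:
- shaft_id: A
  n_contacts: 10
  origin:
  - 0.0
  - 0.0
  - 0.0
  orientation:
  - 0.0
  - 0.0
  - 1.0
  spacing_mm: 5.0
  categories:
  - deep_wm
  - deep_wm
  - shallow_wm
  - gray
  - gray
  - gray
  - gray
  - gray
  - outside
  - outside
- shaft_id: B
  n_contacts: 10
  origin:
  - 30.0
  - 0.0
  - 0.0
  orientation:
  - 0.0
  - 0.0
  - 1.0
  spacing_mm: 5.0
  categories:
  - deep_wm
  - shallow_wm
  - shallow_wm
  - gray
  - gray
  - gray
  - gray
  - gray
  - gray
  - outside
- shaft_id: C
  n_contacts: 10
  origin:
  - 0.0
  - 30.0
  - 0.0
  orientation:
  - 0.0
  - 0.0
  - 1.0
  spacing_mm: 5.0
  categories:
  - deep_wm
  - deep_wm
  - shallow_wm
  - shallow_wm
  - gray
  - gray
  - gray
  - gray
  - outside
  - outside
- shaft_id: D
  n_contacts: 10
  origin:
  - 30.0
  - 30.0
  - 0.0
  orientation:
  - 0.0
  - 0.0
  - 1.0
  spacing_mm: 5.0
  categories:
  - deep_wm
  - shallow_wm
  - gray
  - gray
  - gray
  - gray
  - gray
  - gray
  - outside
  - outside
- shaft_id: E
  n_contacts: 6
  origin:
  - 0.0
  - 60.0
  - 0.0
  orientation:
  - 0.0
  - 0.0
  - 1.0
  spacing_mm: 10.0
  categories:
  - deep_wm
  - shallow_wm
  - gray
  - gray
  - gray
  - outside
- shaft_id: F
  n_contacts: 6
  origin:
  - 30.0
  - 60.0
  - 0.0
  orientation:
  - 0.0
  - 0.0
  - 1.0
  spacing_mm: 10.0
  categories:
  - shallow_wm
  - gray
  - gray
  - gray
  - gray
  - outside
- shaft_id: G
  n_contacts: 6
  origin:
  - 0.0
  - 90.0
  - 0.0
  orientation:
  - 0.0
  - 0.0
  - 1.0
  spacing_mm: 10.0
  categories:
  - deep_wm
  - shallow_wm
  - gray
  - gray
  - outside
  - outside
- shaft_id: H
  n_contacts: 6
  origin:
  - 30.0
  - 90.0
  - 0.0
  orientation:
  - 0.0
  - 0.0
  - 1.0
  spacing_mm: 10.0
  categories:
  - deep_wm
  - gray
  - gray
  - gray
  - gray
  - outside
sources:
- at_contact: A04
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: A05
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: A06
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: A07
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: A08
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: B04
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: B05
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: B06
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: B07
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: B08
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: B09
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: C05
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: C06
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: C07
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: C08
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: D03
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: D04
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: D05
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: D06
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: D07
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: D08
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: E03
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: E04
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: E05
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: F02
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: F03
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: F04
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: F05
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: G03
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: G04
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: H02
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: H03
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: H04
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
- at_contact: H05
  baseline_amp: 5.0
  stim_gain: 2.5
  resp_gain: 2.0
  band:
  - 60.0
  - 140.0
  rise_ms: 100.0
  fall_ms: 100.0
emg:
  locus:
  - 0.0
  - 0.0
  - 58.0
  overt_gain: 300.0
  covert_gain: 75.0
  band:
  - 20.0
  - 300.0
  decay_exponent: 1.0
  rise_ms: 150.0
  fall_ms: 300.0
reference_contact_id: A01
conduction_exponent: 2.0
conduction_floor: 1.0
background_alpha: 1.0
background_rms_uv: 1.5
common_mode_gain: 1.0
rng_seed: 42
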