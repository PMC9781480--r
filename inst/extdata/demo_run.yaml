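# demo pipeline configuration: simulate a three-state system under
# time-lapse imaging, then run the survival and MSD analyses
seed: 3
out_dir: out
stages: [simulate, survival, msd]
meta:
  pixel_size: 0.1
  exposure: 0.2
  dark_interval: 0.3
  n_frames: 200
simulate:
  n_molecules: 500
  states:
    - {label: diffusing, D: 0.5}
    - {label: bound_nonspecific, D: 0}
    - {label: bound_specific, D: 0}
  switch_rates:
    - [0.0, 0.6, 0.4]
    - [0.5, 0.0, 0.0]
    - [0.1, 0.0, 0.0]
  nucleus_radius: 1.0
  localization_sigma: 0.02
  bleach_prob_per_exposure: 0.02
survival:
  r_max: 0.22
  n_min: 3
  correction: intrinsic
msd:
  max_lag: 15
  n_points: 4
  k_max: 3
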