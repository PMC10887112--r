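# Demo device: 2 x 3 microwell grid at 4 um/px, top row empty references,
# bottom row untreated spheroids; dye calibration from the 381/533 ns
# air/nitrogen references.
seed: 1
scene:
  image_shape: [160, 240]
  pixel_size: 4
  chamber_centers:
    - [45, 45]
    - [45, 120]
    - [45, 195]
    - [115, 45]
    - [115, 120]
    - [115, 195]
  chamber_diameter: 200
  chamber_height: 300
  occupancy: [empty, empty, empty, spheroid, spheroid, spheroid]
  spheroid_diameter: 115
acquisition:
  modulation_frequency: 250000
  n_phase_steps: 16
  exposure_time: 0.5
  n_timepoints: 13
  time_interval: 5
  photon_budget: 10000
kinetics:
  o2_initial: 19.2
  o2_plateau: 13.8
  onset_delay: 0
  tau_e_start: 371.3
  reference_drift: 6.4
calibration:
  tau_n: 533
  tau_a: 381
  o2_a: 20.9
groups:
  "4": untreated
  "5": untreated
  "6": untreated
analysis:
  rate_window: 5
  plateau_window: 7
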