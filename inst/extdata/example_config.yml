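# Example pipeline configuration: a two-year-old vase-trained mango in a
# black-clothed 1 x 1 x 2 m chamber under an overhead lamp.
plant:
  n_leaves: 80
  divergence_angles:
    mean: 137.6
    sd: 13.38
  leaf_length_range: [15.0, 22.0]
  leaf_width_range: [4.0, 5.5]
  petiole_length_range: [2.0, 4.0]
  inclination_range: [-30.0, 45.0]
  branch_levels: 2
  branch_lengths: [0.5, 0.35, 0.25]
  branch_diameters: [0.025, 0.015, 0.010]
  branch_tilts: [30.0, 50.0]
  leaf_zone: 0.6
  target_total_leaf_area: 4194.84
  rng_seed: 1
optics:
  leaf: {reflectance: 0.10, transmittance: 0.05}
  stem: {reflectance: 0.15, transmittance: 0.0}
  wall: {reflectance: 0.0, transmittance: 0.0}
  floor: {reflectance: 0.0, transmittance: 0.0}
model:
  p_max: 12.928
  k_light: 0.014
  k_co2: 0.001
  r_dark: 0.889
chamber:
  dimensions: [1.0, 1.0, 2.0]
  air_temperature: 305.15
  pressure: 101325.0
  leak_coefficient: 0.0
  ambient_co2: 400.0
trace:
  n_rays: 1.0e6
  max_impacts: 10
  detector_pitch: 0.005
  seed: 1
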