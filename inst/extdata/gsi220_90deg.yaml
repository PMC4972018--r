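# 220 MeV/u carbon beam on a 12.3 cm PMMA block, large-angle proton
# profile reconstructed at 90 degrees.
seed: 20260901
beam:
  particle: c12
  energy_MeV_u: 220
  entry_point: [0, 0, -7.15]
  direction: [0, 0, 1]
  sigma_beam_cm: 0.4
phantom:
  regions:
    - solid: {type: box, center: [0, 0, 0], half: [2.5, 2.5, 6.15]}
      material: pmma
tracker:
  theta_deg: 90
  distance_cm: 40
  width_cm: 20
  height_cm: 20
  sigma_dir_rad: 0.005
  sigma_point_cm: 0.05
  efficiency: 0.95
analysis:
  n_tracks: 20000
  bin_width_cm: 0.2
  conv_sigma: auto
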