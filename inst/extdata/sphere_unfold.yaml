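# Absorption-unfolding proof of concept: 10 cm PMMA sphere (rho 1.2) with a
# 3 cm low-density (rho 0.6) core; 20 x 20 cm tracker at 40 cm, 90 degrees.
seed: 20260902
beam:
  particle: c12
  energy_MeV_u: 220
  entry_point: [0, 0, -11]
  direction: [0, 0, 1]
  sigma_beam_cm: 0.4
phantom:
  regions:
    - solid: {type: sphere, center: [0, 0, 0], radius: 10}
      material: pmma
      density: 1.2
    - solid: {type: sphere, center: [0, 0, 0], radius: 3}
      material: pmma
      density: 0.6
tracker:
  theta_deg: 90
  distance_cm: 40
  width_cm: 20
  height_cm: 20
  sigma_dir_rad: 0.005
  sigma_point_cm: 0.05
  efficiency: 1
analysis:
  n_tracks: 20000
  bin_width_cm: 0.2
  conv_sigma: auto
unfold:
  enabled: true
  thicknesses: [2.5, 4, 5.5, 7, 8.5, 10]
  n_tracks_per_node: 20000
  degree: 2
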