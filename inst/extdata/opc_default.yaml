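# Default jet-flow OPC characterization run: nominal geometry and the
# standard 138 kPa (20 psi) diaphragm-burst condition.
geometry:
  diameter: 0.6
  total_length: 1.8
  driver_length: 0.20
  aperture_diameter: 0.14
  specimen_standoff: 0.127
burst:
  burst_gauge_pressure: 138000
  petal_duration: 0.0003
  opening_profile: linear_ramp
  shock_fraction: 0.10
numerics:
  n_cells: 720
  t_end: 0.06
sphere:
  diameter: 0.040
  density: 1100
  drag_coefficient: 0.5
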