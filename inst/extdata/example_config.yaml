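# Example configuration: the lower (bottom) borehole of a ~10 cm pine stem
# flushed with dry air at 80 mL/min, wall at fixed xylem equilibrium.
model:
  radius: 5 mm
  stem_diameter: 9.9 cm
  fitting_penetration: 2 cm
  flow: 80 mL/min
  velocity_convention: centerline_double
  temperature: 16.8 C
  pressure: 101325 Pa
  inflow_rh: 0.0
  inflow_d18o: -20
  inflow_d2h: -150
  xylem_d18o: -8.43
  xylem_d2h: -59.28
  case: xylem_equilibrium
  n_segments: 1000
sweep:
  variable: flow
  grid: [10, 20, 40, 80, 160, 320]
  f_mixed: 0.35
synth:
  duration_h: 120
  switch_time_h: 48
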