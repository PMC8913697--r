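# Example traffic-jam scenario on the standard 80 um study pipe.
scenario: reduced_mt
depth: 0.8
region:
  branch: 1
  s: [30, 50]
geometry:
  kind: pipe
  length: 80
  base_radius: 2
  spacing: 4
params:
  alpha: 1.0
  beta: 1.0
  n_time_steps: 8
  T_horizon: 16
n_transverse: 4
axial_density: 0.25
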