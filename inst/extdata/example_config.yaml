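# Example planning configuration: coarse prostate-like scenario.
scenario:
  id: prostate-like
  spacing: 5
  rx_gy: 78
  fractions: 39
machine:
  sigma0: 4
  distal_falloff: 3
  min_mu: 0.02
  rotation_rpm: 1
  spot_switch_s: 0.002
  layer_switch_s: 0.6
objectives: default
sequencing:
  schedule: [20, 10, 5, 2.5]
  keep_layers: 1
  lateral_spacing: 5
  layer_spacing: 0.5
  margin: 5
  angles: [90, 270]
output:
  dir: sparclet-out
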