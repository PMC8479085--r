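# Example run configuration: every key optional, defaults are the assay's.
correction: 0.7
windows:
  tht: [475, 485]
  plateau_h: [32, 48]
savitzky_golay:
  points: 13
  order: 2
  edge: reflect
seed: 1
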