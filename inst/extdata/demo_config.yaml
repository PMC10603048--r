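# Demo pipeline config: a mostly apolar helical receptor carrying one
# lysine and an extended partner carrying one glutamate, assembled at a
# 4 A gap, followed by a bound-complex trajectory and the full
# interface/GBSA analysis.
label: "demo helix-peptide complex"
seed: 1
receptor:
  sequence: KLLALALLALAL
  conformation: helical
  chain: A
  start: 101
partner:
  sequence: ELLALLA
  conformation: extended
  chain: B
  start: 61
complex:
  gap: 4.0
  axis: [0.0, 0.0, 1.0]
trajectory:
  kind: bound
  n_frames: 60
  sigma: 0.15
analysis:
  contact_cutoff: 5.0
  saltbridge_cutoff: 4.0
  n_poses: 5
  engagement_threshold: 8.0
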