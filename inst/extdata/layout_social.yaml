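# Two-chamber social-test arena: 50 x 50 cm at 10 px/cm, radial interaction
# zones of 100 px around each pencil-chamber center.
arena_size_px: [500, 500]
px_per_cm: 10
zone_mode: radial
radial_radius_px: 100
chambers:
  - label: novel
    x: 110
    y: 110
    edge_radius_px: 40
  - label: familiar
    x: 390
    y: 390
    edge_radius_px: 40
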