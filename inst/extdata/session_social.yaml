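# Social recognition-memory protocol: pretest (5 min), sociability (10 min),
# discrimination (5 min); windows are relative to each phase recording.
treatment: saline
phases:
  - label: pretest
    start_s: 0
    end_s: 300
  - label: sociability
    start_s: 300
    end_s: 900
  - label: discrimination
    start_s: 900
    end_s: 1200
stimuli:
  - phase: discrimination
    chamber: novel
    stimulus: novel_mouse
  - phase: discrimination
    chamber: familiar
    stimulus: familiar_mouse
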