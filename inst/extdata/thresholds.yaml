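# Sequential state-classifier presets (logRPKM decision boundaries).
# Rules fire in order active -> poised -> primed; comparisons are strict
# except where primed_inclusive makes the H3K4me1 rule >=.
human:
  active_k27ac: 2.97
  poised_k27me3: 2.0
  primed_k4me1: 1.2
  primed_inclusive: false
mouse:
  active_k27ac: 1.2
  poised_k27me3: 1.25
  primed_k4me1: 0.4
  primed_inclusive: true
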