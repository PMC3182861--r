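# P1, 70 pA depolarizing step from rest: initial response followed by
# regular firing.
params: P1
morphology: surrogate
dt: 0.025
seed: 1
protocol:
  kind: current_step
  amplitude_pA: 70
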