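# P1 held at -57 mV, -150 pA step: rebound burst on release.
params: P1
morphology: surrogate
dt: 0.025
seed: 1
protocol:
  kind: current_step
  amplitude_pA: -150
  holding_mV: -57
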