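# P2 held at -58 mV, -150 pA step: no rebound burst.
params: P2
morphology: surrogate
dt: 0.025
seed: 1
protocol:
  kind: current_step
  amplitude_pA: -150
  holding_mV: -58
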