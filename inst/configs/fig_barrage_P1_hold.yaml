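# P1 held at -57 mV under a 50-synapse GABAergic barrage: rebound burst.
params: P1
morphology: surrogate
dt: 0.025
seed: 7
protocol:
  kind: synaptic_barrage
  holding_mV: -57
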