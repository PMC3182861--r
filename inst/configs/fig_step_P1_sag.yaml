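# P1, -150 pA hyperpolarizing step from rest: Ih sag.
params: P1
morphology: surrogate
dt: 0.025
seed: 1
protocol:
  kind: current_step
  amplitude_pA: -150
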