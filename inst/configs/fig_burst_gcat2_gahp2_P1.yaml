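# P1 with g_CaT and g_AHP doubled, 70 pA: periodic bursting.
params: P1
morphology: surrogate
dt: 0.025
seed: 1
conductance_scale:
  g_CaT: 2
  g_AHP: 2
protocol:
  kind: current_step
  amplitude_pA: 70
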