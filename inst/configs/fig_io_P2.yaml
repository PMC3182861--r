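# P2 I/O series, 900 ms steps.
params: P2
morphology: surrogate
dt: 0.025
seed: 1
protocol:
  kind: io_series
  amplitudes_pA: [35, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85, 90]
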