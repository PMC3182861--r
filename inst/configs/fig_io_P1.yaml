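# P1 I/O series, 900 ms steps.
params: P1
morphology: surrogate
dt: 0.025
seed: 1
protocol:
  kind: io_series
  amplitudes_pA: [50, 52.5, 55, 57.5, 60, 62.5, 65, 67.5, 70, 72.5, 75, 77.5, 80]
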