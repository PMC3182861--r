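# Ih-only voltage-clamp family, -130..-65 mV in 5 mV steps.
params: P1
dt: 0.025
seed: 1
protocol:
  kind: voltage_clamp_series
  ih_only: true
  holding: -40
  commands: [-130, -125, -120, -115, -110, -105, -100, -95, -90, -85, -80, -75, -70, -65]
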