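# dlgnIN

Multi-compartment conductance-based models of local GABAergic interneurons
(INs) of the dorsal lateral geniculate nucleus (dLGN), the thalamic relay
between retina and visual cortex. INs shape the retinogeniculate relay
through feed-forward inhibition, and they fire in strikingly different
modes — tonic trains, initial bursts, periodic bursting, and (in some
cells) rebound bursts after release from hyperpolarization. `dlgnIN` is
for computational neuroscientists who want a tested, scriptable
implementation of a detailed IN model: a branched cable with seven active
conductances (Na, K_dr, I_h, Ca_T, Ca_L, I_AHP, I_CAN), per-compartment
calcium dynamics, somatodendritic channel-density rules, and the analysis
used to characterize such cells electrophysiologically.

The membrane model is Hodgkin–Huxley style on a branched tree,

```
C_m dV/dt = − Σ_c g_c · gates_c · (V − E_c)  −  P_Ca · gates · GHK(V, [Ca]_i, [Ca]_o)
            − g_pas (V − E_pas) + (I_axial + I_inj)/A ,
d[Ca]_i/dt = − α I_Ca − ([Ca]_i − [Ca]_rest)/τ_Ca ,
```

with calcium channels driven by the Goldman–Hodgkin–Katz flux, I_AHP and
I_CAN gated by [Ca]_i, and Ca_T / I_CAN densities growing linearly with
path distance from the soma, g(x) = g_soma (1 + 0.04 x). Two
parameterizations, `P1` and `P2`, reproduce two recorded cells that differ
in passive properties (R_m 22 vs 45 kΩcm², resting −63 vs −69 mV),
channel densities, and spike-threshold shifts; integration is
Crank–Nicolson with a linear-time tree solve (Rcpp).

## Worked example

```r
library(dlgnIN)

morph <- generate_surrogate(morpho_config())   # 9864 um^2, 104 sections
model <- compile_model(morph, parameter_set("P1"))

find_rest(model)
#> [1] -62.99335

input_resistance(model)     # MOhm, -10 pA probe
#> [1] 225.0742

sim <- run_current_step(model, 70)             # 900 ms somatic step
detect_spikes(sim)
#> Spike train: 16 spikes (first 136.0 ms, last 1002.4 ms)

curve <- io_curve(model, seq(50, 80, by = 2.5))
io_slope(curve)              # spikes/pA over the 2-15 spike band
#> [1] 0.5666667

sag <- run_current_step(model, -150)           # Ih sag
sag_ratio(sag)
#> [1] 0.243939
```

`run_current_step(model, -150, holding_mV = -57)` reproduces the
rebound-burst protocol; `run_synaptic_barrage()` replaces the current step
with a 50-synapse GABAergic barrage; `run_voltage_clamp_series()` with
`ih_clamp_model()` plus `fit_ih_activation()` / `fit_ih_tau()` reproduce
the I_h characterization pipeline (Boltzmann midpoint −96 mV, slope 10 mV,
bell-shaped τ_h peaking near 163 ms). `morpho_variant("b")` etc. give the
smaller/larger test morphologies. Reference protocol configurations under
`inst/configs/` run end-to-end through `run_config()`, and
`inst/cli/dlgnin.R` is a thin command-line front-end over the same
functions.

See the vignette (`vignettes/interneuron-model.Rmd`) for the model
equations, unit conventions, the surrogate-morphology construction, and
numerical choices.

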