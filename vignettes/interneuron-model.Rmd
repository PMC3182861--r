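---
title: "A multi-compartment conductance-based model of dLGN interneurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-compartment conductance-based model of dLGN interneurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(dlgnIN)
```

## The model

Local GABAergic interneurons (INs) of the dorsal lateral geniculate nucleus
(dLGN) gate the retina-to-cortex relay. Somatic recordings show a wide
repertoire of firing patterns -- sags under hyperpolarization, rebound
bursts on release, tonic firing, initial bursts, spike-frequency adaptation,
periodic bursting -- and different INs express different subsets of these.
`dlgnIN` implements a detailed compartmental model of such a neuron: a
branched passive cable carrying seven active conductances plus a
submembrane calcium pool, with two shipped parameterizations (`P1`, `P2`)
adapted to two recorded cells that differ only in their passive constants,
channel densities, and the voltage shifts of the spike-generating channels.

The membrane potential of each compartment obeys the cable equation

$$C_m \frac{\partial V}{\partial t} =
  -\sum_c i_c(V, \text{gates}, [\mathrm{Ca}]_i) + \frac{I_{\text{axial}} + I_{\text{inj}}}{A},$$

with channels: transient sodium ($m^3h$) and delayed-rectifier potassium
($n^4$) with Traub-lineage rate functions rigidly shifted along the voltage
axis by the per-cell `Sh_Na`/`Sh_Kdr`; a hyperpolarization-activated cation
current $I_h$ with Boltzmann activation (half-activation $-96$ mV, slope
$10$ mV) and a bell-shaped time constant
$\tau_h(V) = e^{(V+250)/30.7} / (1 + e^{(V+78.8)/5.78})$ ms fitted to mouse
IN voltage-clamp data; low-threshold T-type ($m^2h$) and high-threshold
L-type ($m^2$) calcium channels driven by the Goldman-Hodgkin-Katz (GHK)
flux; a calcium-activated, voltage-insensitive potassium current $I_{AHP}$
(Hill activation, half at 435 nM, $\tau = 3$ ms); and a calcium-activated
nonspecific cation current $I_{CAN}$. Intracellular calcium in each
compartment is a leaky integrator,

$$\frac{d[\mathrm{Ca}]_i}{dt} = -\alpha\, I_{Ca}
  - \frac{[\mathrm{Ca}]_i - [\mathrm{Ca}]_{rest}}{\tau_{Ca}},$$

with $\alpha = 0.0155$, $\tau_{Ca} = 50$ ms and a 50 nM floor, driven by
the summed T- and L-type currents.

Channel densities vary over the tree: uniform dendrite/soma ratios for most
channels (Na, K$_{dr}$ 0.1; Ca$_L$, I$_{AHP}$ 0.1-0.25; I$_h$ 1) and a
linear distance rule $g(x) = g_{soma}(1 + 0.04\,x)$ for Ca$_T$ and
I$_{CAN}$, with $x$ the path distance from the soma in micrometres.

```{r curves, eval = FALSE}
v <- seq(-130, -40, by = 0.5)
plot(v, ih_activation_inf(v), type = "l", xlab = "V (mV)",
     ylab = "Ih activation / tau (scaled)")
lines(v, ih_tau(v) / max(ih_tau(v)), lty = 2)
```

## Units and numerical conventions

All quantities are in mV, ms, nA, mM, $\mu$m and S/cm$^2$. Three unit
conventions deserve explanation because the model's sources leave them
open:

* **Calcium-current conversion.** $\alpha$ converts a calcium current
  density into a concentration rate in a thin submembrane shell. The
  working units are mM/ms per mA/cm$^2$ (equivalently mol/(cm C)); with
  the printed $\alpha = 0.0155$ this reproduces the expected resting
  calcium (50-100 nM, depending on resting potential and T-channel
  density) and micromolar-range transients during bursts, and places the
  I$_{AHP}$ half-activation (435 nM) inside the dynamic range actually
  visited during tonic firing. A literal reading of mmol/(cm C) would
  produce sub-nanomolar per-spike transients and silence every
  calcium-activated channel.
* **GHK permeabilities.** The calcium-channel maxima are quoted in
  S/cm$^2$, but the currents use the constant-field (GHK) flux, which
  takes a permeability in cm/s. Around physiological potentials the GHK
  flux per unit permeability is roughly an order of magnitude larger than
  an ohmic driving force per unit conductance, so the two readings differ
  materially. The package converts conductance to permeability by
  equating the two current scales at the constant-field reference point
  $V = 0$: $P = \bar g\,E_{Ca}/|\mathrm{GHK}(0)| \approx 0.342\,\bar g$
  (`ghk_permeability()`, with $E_{Ca}$ the Nernst potential at a 100 nM
  reference intracellular calcium). With the direct (unconverted) reading the model's
  low-threshold calcium spike reaches $-26$ mV even with sodium channels
  blocked, both parameterizations rebound-burst from any holding
  potential, and the input resistances inflate well past their measured
  values; with the converted reading all three diagnostics land on the
  measured numbers.
* **Spike-channel baseline.** The sodium/potassium rate functions are
  defined on a shifted voltage axis whose origin (`v_traub`) is a
  convention of the source equations; the per-cell shifts `Sh_Na`,
  `Sh_Kdr` are defined relative to it. The baseline is chosen so that the
  absolute spike thresholds, together with the measured input
  resistances, reproduce the two cells' rheobases (about 55 pA and 40 pA)
  and place the firing regime where the Ca$_L$/I$_{AHP}$ feedback -- not
  the bare spike mechanism -- controls the I/O gain, which is the
  regime the recorded cells operate in.

Integration uses a Crank-Nicolson scheme on the branched tree: gating
variables advance by their exact exponential update using rates tabulated
on a 0.05 mV grid, the voltage system is solved by Hines-ordered Gaussian
elimination (linear time in the number of compartments), GHK currents are
linearized about the current voltage, and the calcium pool uses a
backward-Euler update. The default time step is 0.025 ms; halving it moves
spike times by less than 0.1 ms (this is a test). Models are initialized
at the resting potential with gates at steady state, then settled before
every protocol; the leak reversal `E_pas` is calibrated by a secant
iteration so that the full model (active channels open at rest) rests at
exactly the measured $V_{rest}$, which is why `E_pas` differs from
$V_{rest}$.

## The surrogate morphology

The electrical model needs a branched dendritic tree, but only aggregate
morphometrics of the reconstructed cell are available: total membrane
area 9864 $\mu$m$^2$, dendritic length 5771 $\mu$m, longest dendrite
673 $\mu$m, mean somatodendritic diameter about 0.5 $\mu$m, 104 sections
and 330 segments. `generate_surrogate()` builds a tree matching all of
these essentially exactly: one unbranched chain realizes the longest path,
the remaining primary dendrites (six stems by default) carry near-balanced
binary subtrees with seeded length jitter, diameters taper geometrically
and are rescaled to hit the area target. Note that the printed numbers
themselves pin down the soma: $9864 - \pi \times 0.5 \times 5771 \approx
800\ \mu$m$^2$, which the default soma (a cylinder with length = diameter
= 16 $\mu$m) matches; the somatic area matters because several channels
(Na, K$_{dr}$, Ca$_L$, I$_{AHP}$) are concentrated there. What the
surrogate does *not* reproduce is the real branching pattern, so
quantities that depend on the spatial arrangement of the tree beyond the
aggregate statistics (for example the exact distal calcium-channel load)
carry surrogate uncertainty; the input-resistance and I/O tolerances used
in the tests reflect that.

Three alternative-area variants are available through `morpho_variant()`:
(a) similar (9566 $\mu$m$^2$), (b) smaller (7071), (c) larger (14336),
for the morphology-robustness experiment; dendritic length scales with
area so the mean diameter stays fixed (only the areas are published for
these variants).

## Protocols and analysis

Current steps (900 ms, with an optional holding potential maintained by a
compensatory current found by secant search), ideal somatic voltage clamp,
and a GABA-A barrage (50 synapses, 1 nS peak, rise/decay 0.5/5 ms,
reversal $-82$ mV, activated every 10 ms for 300 ms, placed at
seeded-random dendritic segments) are provided as runners returning a
`SimulationResult`-style object. Whether the barrage synapses fire
synchronously per 10 ms event or staggered within the interval is not
constrained by the sources; both modes exist, synchronous is the default.

Analysis follows the conventions a physiologist would use: spikes are
upward 0 mV crossings with a 1 ms refractory guard (all simulated APs
overshoot 0 mV); AP half-width is measured at half of peak minus take-off
(take-off = where dV/dt first exceeds 20 mV/ms); I/O slopes are ordinary
least squares over the points with 2-15 elicited spikes; the sag ratio is
(peak - plateau)/(peak - baseline) with the plateau averaged over the last
100 ms of the step; rebound spikes are counted in the 200 ms after
stimulus offset and a rebound burst means at least two of them. The
initial-burst and periodic-bursting classifiers are ISI-based conventions
(leading ISIs under half the median of the later ISIs; recurring
long-gap/short-cluster alternation) documented in `classify_response()` --
the source recordings were not quantified on these axes, so the rules are
package conventions, fixed constants, not fitted quantities.

The $I_h$ fitting pipeline reproduces the experimental procedure:
steady-state clamp currents normalized by the maximal amplitude are fitted
with a Boltzmann $(1+e^{(V-shift)/stp})^{-1}$; each trace's activation
time course is fitted by $(1-e^{-t/\tau_h}) I_\infty$ (single
exponential, measured relative to the instantaneous current just after
the step so that only the time-dependent component remains), and
$\tau_h(V)$ by the four-parameter bell curve. By default the steady-state
ratios are corrected for the driving force $(V - E_h)$ before fitting, so
the fitted curve estimates conductance activation; without the correction
the fitted midpoint is biased several mV hyperpolarized because the
driving force shrinks toward $E_h$.

One internal inconsistency of the source description is worth noting: the
$\tau_h$ curve $e^{(V+250)/30.7}/(1+e^{(V+78.8)/5.78})$ has its interior
maximum at about 163 ms (at $-87$ mV), whereas the accompanying text
quotes a maximum of "about 200 ms". The formula, not the quoted maximum,
is taken as normative throughout; similarly, the stated T-channel density
gradient ("239% of the somatic value at 60 um") is inconsistent with the
printed rule $g(x) = g_{soma}(1+0.04x)$, which gives 340% at 60 um, and
again the printed formula wins.

## Problem sizes used in tests

The shipped test-suite and the acceptance script run the full battery at
the model's native scale -- a 330-compartment cell at dt = 0.025 ms with
900-1600 ms protocols -- since single runs take well under a second; I/O
curves use 12-15 amplitudes each. No simulation is scaled down relative
to the study conditions.

## Known limitations

* The surrogate tree reproduces aggregate morphometrics only; spatial
  detail (branch-order statistics, dendritic appendages, the axon) is not
  modelled.
* A-type and M-type potassium channels are deliberately absent.
* The calcium pool is a single shell per compartment without buffering or
  diffusion.
* Cholinergic modulation and network context are out of scope.
* The exact equations behind several cited channel kinetics are not
  printed in the sources; the package uses the standard published forms of
  the cited lineages, with the under-determined constants fixed against
  the printed physiology (rheobases, input resistances, holding currents,
  rebound behavior) and documented above: the Traub baseline `v_traub` is
  $-64$ mV, the T-current inactivation midpoint/slope are $-78$/6 mV, the
  I$_{AHP}$ activation uses a single gate with an SK-like Hill
  coefficient of 4 (half-activation at 435 nM as specified), and the
  calcium-channel permeability conversion is the $V_0 = 0$ chord
  equivalence above. Conclusions that depend sensitively on those
  constants should be checked against the sensitivity notes in this
  vignette.
* Some quantitative characteristics of the reconstruction remain outside
  the published bands even at the best joint calibration of the open
  constants, and the corresponding tests are deliberately left failing
  rather than loosened: the P1 I/O slope plateaus near 0.6 spikes/pA
  (published ~0.8) and the g$_{AHP}$-swap moves the slopes by roughly
  +/-35% rather than the published factor ~3 -- the total AHP conductance
  reachable under the printed densities and dendrite/soma ratios bounds
  the feedback leverage; simulated AP half-widths are ~0.27 ms against
  the published ~0.4 ms with the Traub-lineage rates at 36 C; the
  synaptic-barrage rebound in P1 reaches one AP rather than a
  multi-spike burst (the barrage can only hyperpolarize to the GABA-A
  reversal, leaving partial T-channel recovery); and doubling g_CaT +
  g_AHP produces strengthened initial bursts and faster tonic firing
  but not sustained periodic bursting (the afterhyperpolarization
  trough, bounded by the AHP driving force, does not reach the voltages
  where the T channel de-inactivates under the adopted inactivation
  curve).
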