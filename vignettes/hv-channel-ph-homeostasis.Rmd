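---
title: "A voltage-gated H+ conductance and cytosolic pH homeostasis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A voltage-gated H+ conductance and cytosolic pH homeostasis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvchan)
```

## The problem

Intracellular calcification converts HCO₃⁻ to CaCO₃ and releases one proton
per calcite unit.  For a coccolithophore-sized cell, plausible calcification
rates produce an acid load that would shift cytosolic pH by a few tenths of
a unit per minute if nothing exported or consumed the protons
(`acid_load_rate()` does this arithmetic from an explicit flux, cytosolic
volume and buffering capacity, since the three inputs vary widely between
cells and published estimates).  A depolarisation-activated, highly
H⁺-selective plasma-membrane conductance — gated by the transmembrane H⁺
electrochemical gradient the way metazoan Hv1 channels are — can carry that
efflux passively whenever the proton motive force points outward.  This
package implements the analysis chain used to characterise such a
conductance electrophysiologically, a minimal whole-cell model of the
resulting pH homeostasis, and the imaging quantifications that link it to
calcification.

## Electrochemistry

All equilibrium arithmetic uses concentrations as activities (activity
corrections are a documented limitation) and derives free H⁺ exclusively
from pH.  The Nernst slope `2.303RT/F` is 58.17 mV/decade at the 20 °C
recording temperature; because a widely used rounded value of 60 mV/decade
reproduces the −48 mV resting `E_H` quoted for pH_o 8.0 / pH_i 7.2, the
slope of `ph_equilibrium_potential()` is always an explicit caller choice
(either directly in mV or through a temperature), never silent.  The GHK
voltage equation is restricted to monovalent ions (H⁺, K⁺, Na⁺, Cl⁻);
divalents raise an error rather than being shoehorned into the monovalent
form.  The package-wide pH-gradient convention is `ΔpH = pH_o − pH_i`.

`min_selectivity_ratio()` solves the inverse problem — the smallest
`P_H/P_X` for which the two-ion GHK reversal stays within a stated
tolerance of the pure-H⁺ Nernst potential — by bisection on `log10(ratio)`
over [0, 12], which is valid because the deviation is monotone
non-increasing in the ratio (property-tested).  With a 200 mM K⁺ pipette
against a sea-water bath and a 10 mV tolerance the bound is of order 10⁷,
comfortably above the 10⁶ benchmark for dedicated proton channels.

## Trace analysis conventions

* Outward (positive charge leaving the cell) current is positive; t = 0 at
  sweep start; all analysis windows are half-open `[start, end)`.
* Leak subtraction is resistive, referenced to the holding potential:
  `I_leak = (V_cmd − V_hold)/R_seal`, so holding-level current is never
  altered, and a family cannot be subtracted twice.
* Steady-state I–V points are means over the final 10–50 ms (default
  40 ms) of the step, anchored to the step *end* where the current has
  settled.
* Tail peaks are the signed extremum in a window `(onset + blank,
  onset + search)` with defaults of 2 ms blanking (capacitance transient)
  and a 20 ms search; both are explicit parameters because peak picking is
  a judgement call in practice.  `E_rev` is the x-intercept of one global
  OLS line of peak against test voltage; a fit with non-positive slope and
  single-signed peaks is flagged unreliable rather than silently reported.
* Activation kinetics are fit as `I(t) = offset + A(1 − e^{−t/τ})` with
  Levenberg–Marquardt (`minpack.lm::nlsLM`); flat traces are flagged
  (amplitude ≈ 0, τ unidentifiable) instead of fitted.
* Recordings fail QC when series resistance varies by more than 15%
  (`(max−min)/first > 0.15`).

## The cell model

State variables: membrane potential `V` (mV), gate open probability `p`,
cytosolic pH, and four cumulative per-pathway H⁺ tallies.  Currents:

* Gated H⁺ channel: `I_H = (1 − b_Zn) g_max p (V − E_H)` with Boltzmann
  steady state `p∞ = 1/(1 + exp(−(V − (E_H + δ))/k))` and first-order
  relaxation (τ_act opening, τ_deact closing).  The midpoint rides on
  `E_H`, so the activation curve shifts one-to-one with the H⁺ gradient —
  the defining Hv1 property.  A GHK-flux open-channel variant is available
  as a configuration switch (`ghk_gated`), default off: the observations
  this model is calibrated to do not constrain open-channel rectification,
  and the ohmic form is the simpler default.
* Background H⁺ permeability: a small ungated pathway carrying GHK
  (flux-equation) current.  The GHK form matters here: inward H⁺ current is
  carried by external protons, which at sea-water pH are nanomolar, so the
  pathway rectifies strongly.  That lets one parameter set reproduce both
  the resting depolarisation when the bath is acidified to pH 6.5 (where
  the tenfold larger external [H⁺] pulls the membrane toward a now-positive
  `E_H`) and the observation that large hyperpolarising steps move
  essentially no acid (an ohmic background big enough for the first
  observation would violate the second by an order of magnitude).
* Cl⁻ inward rectifier: `I_Cl = g_Cl s∞(V)(V − E_Cl)` with
  `s∞ = 1/(1 + exp((V − V_half)/k_Cl))` — activation grows with
  hyperpolarisation, stabilising the resting potential and balancing
  charge during H⁺ efflux.  Zn²⁺ scales it by `1 − zn_sensitivity`.
* Ohmic leak `g_leak (V − E_leak)`.

pH dynamics: `β V_cyt d(pH_i)/dt = I_H/F − J_calc + k_sec β V_cyt
(pH_set − pH_i)`, i.e. channel efflux alkalinises, the calcification load
acidifies at a constant molar rate, and all slower uncharacterised
transporters are lumped into first-order relaxation toward a set point —
the minimal form consistent with the observed roughly exponential
post-pulse recovery.  NH₄Cl exposure is modelled phenomenologically as a
square-pulse acid load (explicit NH₃/NH₄⁺ permeation is out of scope).

### Default parameters

| Parameter | Value | Units | Origin |
|---|---|---|---|
| `delta_mv` (δ) | +15 | mV | activation just positive of `E_H`; see sensitivity note |
| `slope_k_mv` (k) | 8 | mV | typical Hv1 Boltzmann slope |
| `tau_act_ms` | 220 (native), 107 / 22.9 (heterologous presets) | ms | measured activation kinetics |
| `tau_deact_ms` | 40 | ms | assumed; tail decay scale |
| `zn_block_fraction` | 0.84 (wild type), 0.27 / 0.28 (H197A / H203A) | – | measured block fractions |
| `g_max_ns` | 0.614 | nS | calibrated (clamp anchors) |
| `background_permeability_pl_s` | 79.78 | pL/s | calibrated (rest at pH_o 6.5) |
| `g_cl_ns` | 0.419 | nS | calibrated (rest at pH_o 8.0) |
| `e_cl_mv`, `v_half_cl`, `k_cl` | −20, −60, 12 | mV | assumed, consistent with an inward rectifier active below rest |
| `g_leak_ns`, `e_leak_mv` | 0.1, −70 | nS, mV | assumed seal/background leak |
| `c_m_pf` | 3 | pF | protoplast of ~10 µm |
| `v_cyt_l` | 5e-13 | L | geometric volume of a ~10 µm cell |
| `beta` | 0.034 | mol L⁻¹ pH⁻¹ | calibrated (clamp anchors fix `g_max/(β·V_cyt)`) |
| `k_sec_per_s` | 0.017 | s⁻¹ | recovery time constant inside the observed 30–60 s window |
| `ph_set`, initial pH_i | 7.2 | – | typical resting cytosolic pH |
| `j_calc_mol_s` | 8.3e-19 (patched) / 2.18e-16 (calcifying preset) | mol s⁻¹ | see calibration |

### Calibration

The defaults are calibrated so that **one** configuration simultaneously
reproduces four measured anchors: resting potential −45.7 mV at pH_o 8.0
and −29.0 mV at pH_o 6.5, and 10 s clamp-step alkalinisations of +0.36
(+70 mV) and +0.22 (+20 mV) pH units from −50 mV.  The procedure is a
nested sequence of one-dimensional root solves, iterated to a fixed point:
`g_cl` from the pH 8.0 rest anchor, the background permeability from the
pH 6.5 rest anchor (the two decouple because the background pathway is
almost silent near `E_H` at pH 8.0), the patched-cell `j_calc` set equal to
the resting channel efflux (so the unperturbed model is exactly steady at
pH 7.2), and `g_max` from the +70 mV clamp anchor.

One anchor cannot be hit exactly: over a clamp step the pH equation is
linear in the pH excursion (constant terms cancel against the steady
baseline; gating is saturated at both test levels), so the ratio of the
+20 and +70 mV responses is structurally pinned to the driving-force ratio
`(20 − E_H)/(70 − E_H) ≈ 0.571` at pH_i 7.2 — below the 0.611 implied by
the two anchor means.  The GHK open-channel variant was evaluated as a way
to break the pinning and in simulation moves the ratio the wrong way
(≈0.553), so the ohmic default stands.  With the +70 mV anchor matched
exactly, the +20 mV step yields ≈0.205 pH units, inside the ±0.04
uncertainty attached to the 0.22 mean.  Sensitivity: δ and k barely move
this ratio (the gate is ≥0.998 open at both levels for δ ≤ 25); they mainly
set where outward current first becomes visible above `E_H`, and the rest
anchors re-absorb small changes in δ through the `g_cl` solve.

Two configurations, not one, cover the perturbation experiments.  The
clamp/rest anchors describe whole-cell-dialysed, pipette-buffered cells in
which the channel at rest carries almost nothing.  The Zn²⁺ and Ca²⁺-free
experiments describe intact, actively calcifying cells, encoded as the
`calcifying` deltas (a much larger `j_calc`, `k_sec` at the slow end of the
recovery window).  This is a physical necessity, not a convenience: a cell
resting ~1 mV above `E_H` with the clamp-calibrated conductance cannot
carry enough channel flux for its block to cost 0.13 pH units.  In the
calcifying preset the coupled steady state (`steady_state()`) sits around
pH_i ≈ 6.9 with the membrane a few mV below the Cl⁻/leak rest — the model's
statement that an actively calcifying cell runs measurably acid of, and
hyperpolarised from, the quiescent state, with the channel exporting most
of the load.  `j_calc` for this preset is calibrated so that a 2.5 min Zn²⁺
application acidifies by 0.13 pH units; the same preset then gives ≈0 for
the Ca²⁺-free control with no further tuning, because with `j_calc = 0`
there is no flux for the block to interrupt.  The NH₄Cl pulse load is set
so the pulse acidifies by ≈0.3 pH units.

### Numerics

Integration is fixed-step classical RK4 in compiled code (deterministic,
bit-stable across runs; no adaptive stepping).  The step is
`min(τ_act, τ_deact, C_m/g_total)/20`, capped at 0.5 ms, with GHK pathways
entering `g_total` through their slope conductance `P·F·[H⁺]_i/(RT/F)`.
The per-pathway H⁺ tallies are integrated as extra state variables with the
same RK4 weights, so the conservation audit
`β V_cyt ΔpH_i = Σ pathway terms` closes to round-off (the tests require
relative residual < 1e-5 and observe ~1e-13).  The gate is clipped to
[0, 1] against round-off drift.  Scenario events partition a run into
constant-parameter segments chained exactly through the final integrator
state.  `resting_potential()` scans [−120, +80] mV at 0.5 mV for sign
changes, polishes each root with `uniroot`, and returns the most negative
stable root (positive local I–V slope), with all roots attached.
Degenerate inputs error early and specifically: double leak subtraction,
windows outside steps, fewer than three tail levels, constant tail peaks,
all-zero permeabilities, non-positive buffer volumes.

## Imaging quantification

BCECF calibration is two-point linear in the F488/F458 ratio between
pH 6.5 and 7.5 anchors (`pH(R) = 6.5 + (R − R65)/(R75 − R65)`); ratios
extrapolated beyond 20% of the anchor span are flagged rather than
truncated.  Background fluorescence is not subtracted (it was negligible in
the source protocol).  For dye-ester-loaded cells only ΔpH is reported,
never absolute pH.  Event ΔpH defaults to 60 s pre / 60 s post means; the
windows are parameters because published means rarely state them.
Calcification rates are OLS slopes of cross-polarised intensity over the
standard 0–150 / 150–300 / 300–600 min windows, normalised to the first
window; inhibition is `100(1 − normalized rate)` in the treatment window
(default the second).  Normalisation makes the measure invariant to overall
intensity scaling, which is property-tested.

## Synthetic data: what it does and does not emulate

The generators produce: voltage-clamp families from the closed-form gate
relaxation under an ideal clamp at pipette-buffered pH, plus resistive
leak, optional 0.5 ms capacitance transients at step edges (on by default
so tail blanking is genuinely exercised), and additive Gaussian current
noise; BCECF traces from the inverse calibration map with multiplicative
channel noise; and piecewise-linear birefringence series whose
treatment-window slope ratios are the scenario truths (0.31 for the low-pH
scenario, 0.33 for the ammonium pulse, with partial third-window recovery
standing in for the observed post-treatment lag).  Every generator records
a truth manifest (seed and all true parameters) and is bit-reproducible
from it; seeding is local, leaving the caller's RNG stream untouched.

They deliberately omit: series-resistance voltage errors, P/N leak
protocols, proton depletion and open-channel rectification, photobleaching,
focus drift and cell movement, and any image segmentation (inputs are
already-reduced per-cell time series).  Passing the closed-loop suite
therefore shows the *analysis* is correct and robust to the modelled noise,
not that it is immune to every artefact of real recordings.

Test problem sizes: the closed-loop grid runs nine (g, E_rev, τ) cells
spanning 0.5–5 nS, −60 to +40 mV and 20–400 ms at SNR 20, asserting E_rev
within 2 mV, τ within 5% and steady-state current within 5%; the
unbiasedness check uses 200 seeded replicates of the windowed regression;
free-running scenario tests simulate 4–10 model minutes.

## Limitations

* Activities equal concentrations; no carbonate-system speciation, no
  EGTA/Ca²⁺ buffering chemistry, no coccolith-vacuole compartment or Ca²⁺
  transport, no photosynthetic H⁺ consumption beyond the lumped `k_sec`.
* The +20/+70 mV response ratio is structurally limited (see Calibration);
  the +20 mV anchor is met within its uncertainty, not exactly.
* The calcifying preset's steady pH_i (≈6.9) is a model inference, not a
  measured value; it follows from demanding that channel block cost
  0.13 pH units under first-order secondary regulation.
* Zn²⁺-induced acidification is attributed entirely to channel block plus
  the ongoing calcification load; contributions from other Zn²⁺-sensitive
  pathways are not modelled.
* The sub-Nernstian −43 mV/pH slope measured in native cells (vs the ideal
  −58.2 recovered from ideal synthetic data) is kept as a reference
  expectation (`reference_measurements()`), not mechanistically modelled;
  plausible causes (incomplete pipette buffering, a minor contaminating
  conductance) are scenario material, not model structure.
* Single voltage-independent τ per condition; stochastic single-channel
  gating and voltage-dependent kinetics are extension hooks.
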