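---
title: "State-dependent GABAergic control of SPN dendrites: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-dependent GABAergic control of SPN dendrites: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model, its
assumptions, the parameters that matter, what the synthetic generators do
and do not emulate, and the numerical and design choices that were
genuinely open. Every number quoted here is computed by the test suite or
the `analysis/` scripts; nothing is asserted that the code does not
measure.

## The scientific question

Striatal spiny projection neurons rest in a "down-state" near −84 mV,
pinned there by constitutively open Kir2 potassium channels. The GABA-A
reversal potential in these cells is near −60 mV — more than 20 mV above
rest — so a GABA-A conductance opening from the down-state *depolarizes*
the neuron even though it is conventionally called inhibitory. Clustered
glutamatergic input to a distal dendrite can trigger an NMDA-receptor-
dependent plateau potential (a "dendritic spike" or local up-state lasting
~50–200 ms). Whether GABA-A input promotes or suppresses that plateau
turns out to depend on *where* the GABA arrives (on the stimulated
dendrite or elsewhere) and *when* (before the cluster, or during the
plateau). The package reproduces this state-dependence in a calibrated
biophysical model and quantifies it with the plateau metrics below.

## The model

**Morphology.** `generate_morphology()` builds a stylized dSPN: a
spherical soma (radius 6.010 µm) and 4 primary dendrites that bifurcate at
three levels (60 sections). Only aggregate properties of a reconstructed dSPN are published, so those
are the calibration surface: total dendritic length chosen so that spine placement
at 1.711 µm⁻¹ beyond a 30 µm floor yields ~5,500 spines; the deepest
root-to-tip path stretched to 265.268 µm; per-level diameter taper scaled
so whole-cell capacitance (soma + dendrites + spines, 1 µF/cm²) is exactly
180 pF; ~700 dendritic segments (4.75 µm target). Section lengths carry a
±25% uniform jitter and are rescaled to the exact totals, so different
seeds give different trees on the same calibration surface. Two structural
notes: a 4→8→16 tree cannot supply the ≥50 spiny test dendrites the
distance scan requires, hence the third bifurcation level; and a 3 µm
segment cap would give ~1,100 segments, so the published 700-segment
compartmentalization was preferred.

**Membrane.** Fourteen somatodendritic channels with spatial density
rules (sigmoidal/exponential/uniform in path distance) live in
`inst/extdata/channels.yaml`, and the gating schemes (Boltzmann steady
states, bell-shaped time constants; a calcium-Hill gate for SK; a
voltage-and-calcium gate for BK; GHK flux for the calcium channels) in
`inst/extdata/kinetics.yaml`. Published striatal models ship this level of
machinery as code rather than tables, so the parameterization here is the
package's own, constrained by the published physiology: rest −84 mV,
rectified-range input resistance ≈85 MΩ under a −200 pA step, membrane
time constant ≈10.5 ms, an up-state threshold of 15 clustered inputs, a
GABA-synapse threshold of 9 in the distributed mode, and a tonic boosting
band ending at 3×10⁻⁴ S/cm². Because everything is data, substituting a
different published parameter set requires no code change. Functionally
the important gradients are: Kir uniform (1×10⁻⁴ S/cm²) — it sets the
down-state and the input resistance and its closure with depolarization
underlies both the boosting of distal excitability and the compensation of
remote shunts; Kaf sigmoidally declining with distance — proximal A-type
current vetoes plateau initiation, its distal decline permits it; CaV1.3
and the CaV3.x channels rising distally — their slow, low-threshold inward
current is what converts a sustained few-mV baseline depolarization
(leading off-site GABA, or tonic GABA) into full plateau regeneration
rather than a graded lingering response. The leak conductance of every
compartment is solved at build time so the assembled cell is exactly at
rest at −84 mV with all channels at steady state (e_pas −70 mV); this is
the model's calibration contract, not a tuning loop at run time.

**Synapses.** Two-state kinetic conductances, peak-normalized:
`g(t) = g_max·N·(e^{−t/τ₂} − e^{−t/τ₁})`. AMPA 350 pS (1.9/4.8 ms, 0 mV)
and NMDA 752.5 pS (5.5/231 ms, 0 mV) are co-located on each stimulated
spine head; NMDA carries a Jahr–Stevens-type magnesium block
(k = 3.57 mM, γ = 0.062 mV⁻¹, [Mg] = 1 mM). GABA-A synapses are 1000 pS
(0.5/7.5 ms) reversing at −60 mV, placed on dendritic shafts. Tonic GABA
is a uniform somatodendritic conductance at −60 mV, *set* (not
accumulated) by `apply_tonic()`. The NMDA decay constant keeps plateau
durations inside the 50–200 ms up-state range, which the distance scan
confirms (plateau quarterdrops 42–172 ms).

**Numerics.** Backward Euler on the Hines-ordered tree: unconditionally
stable, O(compartments) per step, dt = 0.025 ms. Gates advance by
Rush–Larsen exponential updates from voltage lookup tables (0.05 mV grid);
GHK and the magnesium block are evaluated at the previous step's voltage.
Unstimulated spines are folded into their parent segment by scaling its
membrane area by `1 + spine_area/segment_area`, which conserves whole-cell
capacitance to <1%; stimulated spines are explicit neck+head compartments
(neck 1 µm × 0.1 µm, head 0.5 µm × 0.5 µm). Every protocol starts from a
settled state: the base model settles 1000 ms once and is cached;
protocols that add spines restore that state and re-equilibrate 100 ms;
tonic conditions re-settle fully because they change the resting point.
Halving dt moves subthreshold protocol traces by <0.1 mV; regenerative
transitions are knife-edge events, so at plateau collapse the shift can
reach ~0.2 mV (a timing, not amplitude, sensitivity) — the convergence
test asserts both. The passive solver was verified against closed forms:
Ohmic steps, RC time constant and 10 Hz impedance on a sphere, cosh
attenuation on a sealed cable, superposition, and charge-budget closure.

## Protocols and metrics

* `clustered_glutamate()` — n spines activated at 1 ms intervals moving
  distally from two-thirds of the section length.
* `phasic_gaba()` — `onsite` (bursts of 3 × 4 at 1 ms on the stimulated
  dendrite), `offsite4x3` (4 distal off-path dendrites × burst of 3),
  `offsite12x1` (single synchronous synapse on each of the 12 most distal
  dendrites), `onpath_proximal` (the parent section). On-site GABA is
  placed at the midpoint of the *stimulated spine span* rather than of the
  whole section: on a synthetic tree whose terminal sections run 60–75 µm
  the two readings of "the stimulated dendrite's midpoint" diverge, and
  only a co-located shunt reproduces plateau truncation — placed at the
  section midpoint, 15 µm away, the axial resupply from the NMDA core
  re-ignites the plateau once the GABA transient ends.
* `timing_sweep()` — Δt = t_GLUT − t_GABA (negative: glutamate first);
  GABA fixed, glutamate shifted; the two reference runs are shared.
* **Quarterdrop**: time from the last stimulus until the voltage has
  dropped one quarter of its peak amplitude; the drop is sought after the
  trace peak because boosted plateaus peak well after the last stimulus.
  A response is a dendritic spike when quarterdrop ≥ 40 ms — the cutoff
  sits in the gap of the bimodal quarterdrop distribution over all 56
  scanned dendrites (EPSPs ≤ 39 ms, plateaus ≥ 42 ms) and lives in the
  classifier's argument list, not in code.
* **P1/P2/P3**: P1 = glutamate-alone peak over baseline; at the combined
  response's peak time, P3 is measured from baseline and P2 from the
  underlying GABA-alone potential. P2/P1 < 1 is shunting; ≥ 1 summation.
* `threshold_search()` — smallest input count classified as a spike;
  "just-subthreshold" clusters are threshold−1 on the same morphology,
  not a hard-coded 15.
* `measure_impedance()` — 5 pA sinusoid at 10 Hz, last cycles projected
  on the quadrature pair (a linearized transfer matrix was the
  alternative; the injected probe matches what an experiment would do and
  works with active conductances at their operating point). The
  GABA-load experiment holds N synaptic peak conductances open as a
  steady local shunt — a stationary rendering of a phasic quantity chosen
  so impedance is well-defined at 10 Hz. Off-site loads change the local
  impedance by ~20% at 12 synapses (Kir closure under the accompanying
  depolarization offsets part of the added conductance, but incompletely)
  versus an ~80% on-site collapse.

## Synthetic data: what it does and does not emulate

`gen_ephys_dataset()` mimics the *structure* of perforated-patch reversal
measurements — a linear response through the true reversal with Gaussian
noise per cell per potential on a 5 mV grid — with defaults (slope 0.7,
noise 3.7, 5 cells) chosen once to land the per-voltage-mean regression in
the R² ≈ 0.9 regime of real fits. It does not emulate series-resistance
artifacts, cell-to-cell slope heterogeneity, or drift. A note on recovery:
with 5 potentials and 5 cells in this noise regime, the x-intercept
estimator's spread is ~1.05 mV (sd), so the *mean* recovery error over
200 seeds is well within ±1.5 mV (and the bias ~0), but no estimator
could put 95% of single-study errors inside ±1.5 mV at R² ≈ 0.9 — the
Monte-Carlo test asserts the mean, the bias, and the actual 95% quantile
(~2.2 mV).

The morphology generator likewise reproduces aggregate calibration
targets, not the reconstructed cell: passing tests show the *mechanisms*
(state-dependent GABA action, locality of shunting, NMDA dependence) are
properties of the calibrated model class, not of one tree. Quantities
tied to one cell's branch geometry — which dendrites spike at 18 inputs,
the exact Δt window edges — should be read as one member of that class.
On this tree, 18-input plateaus appear only on terminal branches beyond
~175 µm (the published distance dependence puts spikes beyond ~100 µm; branch-point
loads on the synthetic tree push the transition further out), and the low-Ra variant
(100 Ω·cm with AMPA/NMDA ×1.6) holds the threshold at 16 versus 15 — the
same "qualitatively preserved" behaviour, one input off.

## Known limitations

* Gating kinetics are a plausible HH parameterization constrained by the
  printed physiology, not a transcription of the antecedent model's rate
  functions; all of it is swappable data.
* The calcium pool is a single-exponential shell (50 nM rest, 20 ms
  decay, 0.1 µm depth) feeding SK/BK — the simplest scheme supporting
  calcium-activated K⁺ channels.
* No axon and no somatic action-potential readout; the modeled readouts
  are dendritic and somatic subthreshold potentials.
* Short-term plasticity, receptor desensitization and GABA-B are out of
  scope (the experiments the model mirrors blocked GABA-B).
* The exact Wilcoxon implementation enumerates 2^n sign assignments and
  is intentionally capped at n ≤ 25.
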