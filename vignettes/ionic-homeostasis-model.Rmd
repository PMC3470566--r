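---
title: "A compartmental CA1 neuron model with full ionic homeostasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A compartmental CA1 neuron model with full ionic homeostasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionshift)
```

## The problem

GABA is the principal inhibitory transmitter of the adult brain, yet
high-frequency activation of GABA~A~ receptors on hippocampal CA1 pyramidal
neurons can produce a paradoxical biphasic response: a fast hyperpolarization
followed by a slow depolarization strong enough to fire the cell. The
candidate mechanisms are coupled. GABA~A~ receptors pass both Cl^-^ and
HCO~3~^-^ (permeability ratio 4:1), so their reversal potential
`E_GABA = 0.8 E_Cl + 0.2 E_HCO3` sits above `E_Cl`; intense stimulation loads
small dendrites with chloride, depolarizing `E_GABA`; the K^+^--Cl^-^
cotransporter KCC2 then extrudes that chloride together with potassium,
raising extracellular K^+^, which both depolarizes the membrane directly and
throttles further chloride extrusion. Disentangling these pathways
experimentally is hard precisely because KCC2 couples them. ionshift
implements a biophysically detailed single-cell model in which every pathway
is explicit and can be toggled, clamped, or scaled independently.

## Model structure

A neuron is a rooted tree of cylindrical compartments (SWC input or synthetic
fixtures). Each compartment carries:

* a membrane potential obeying the cable equation, integrated with the
  implicit Euler method at `dt = 0.02` ms on the branched tree (direct
  Hines-ordered solve, so the linear algebra is exact);
* dynamic intra- and extracellular concentrations of Na^+^, K^+^, Cl^-^ and
  Ca^2+^; the extracellular pool is a thin shell whose volume is 15% of the
  intracellular volume (protocols may override the fraction). HCO~3~^-^ is
  fixed (15 mM in, 25 mM out);
* voltage-gated channels: two fast-Na Markov schemes (a 5-state scheme
  without and a 6-state scheme with slow inactivation, mixed according to the
  linear distance gradient `fraction = distance/250 µm`, saturating at
  250 µm; the soma and axon carry only the 5-state scheme), a delayed
  rectifier, A-type and M-type potassium currents, an h-current, and an
  L-type calcium channel, all as parameterized gating specs;
* a 6-state GABA~A~ receptor scheme (unbound, singly and doubly bound, open,
  and one desensitized state off each bound closed state) driven by
  transmitter pulse trains; synapses are placed at layer-specific densities
  (1.7 µm^-1^ on the soma and proximal apical dendrites, 0.5 in medial thick
  radiatum, 0.15 in distal/thin radiatum, 0.12 in lacunosum-moleculare, 0.61
  and 0.1 in proximal and distal oriens), each synapse contributing a 1 nS
  quantal conductance;
* transport and homeostasis: KCC2 (2-state electroneutral carrier; zero flux
  exactly at `[K]i[Cl]i = [K]o[Cl]o`), NKCC1 (two-faced carrier with a
  dynamic outward-facing fraction; currents `-0.5, -0.5, +1` times the
  carrier current for Na, K, Cl), the Na/K-ATPase (3:-2 stoichiometry with
  saturating substrate dependence), a plasma-membrane calcium pump and the
  Na/Ca exchanger (3:-2), ohmic Na^+^ and K^+^ leaks, first-order glial
  buffering of shell K^+^, and longitudinal diffusion of all ions in both
  pools.

Reversal potentials are recomputed from the Nernst equation every step at
32 °C (slice-bath convention; configurable — the temperature is a modelling
choice, not a measured constant of the system).

### Units

mV, ms, mM, cm, S/cm^2^, mA/cm^2^. With these, `I = g (V - E)` needs no
conversion factor, and `d[X]/dt = -I A / (z F Vol)` converts currents to
concentration changes. The longitudinal diffusion constants are
`D_Na = 1.33, D_K = 1.96, D_Cl = 2.08, D_Ca = 0.60` in µm^2^/ms (equivalently
1e-5 cm^2^/s, the standard aqueous-ion magnitudes).

## The calibration algorithm

A model at rest must have zero net flux for every ion in every compartment;
otherwise concentrations (and therefore the resting potential) drift.
`balance_rest()` enforces this at -66 mV:

1. the Na/Ca exchanger scale is solved so that exchanger, calcium pump and
   calcium-channel fluxes cancel;
2. the NKCC1 density is solved so chloride loading balances resting KCC2
   extrusion (the chloride leak defaults to zero);
3. the minimum Na/K pump rate that would balance the remaining sodium influx
   is computed, and the pump is set 20% above that minimum;
4. sodium and potassium leak conductances close the balance exactly.

The 20% margin is not cosmetic: the extra pumping must be offset by a
potassium leak, and it is that leak headroom which lets the cell depolarize
when extracellular potassium rises (`check_k_sensitivity()` measures the
response to a +4 mM step; with zero margin the potassium leak collapses and
the response shrinks — this is asserted in the tests). Because every
compartment is balanced at a common potential, axial currents vanish and the
whole tree rests at -66 mV with zero drift by construction; the test suite
verifies drift below 0.01 mV/s in simulation.

Two one-parameter fits complete the calibration surface: `fit_kcc2_density()`
matches the simulated dendritic chloride clearance (monitored ~200 µm from
the soma after a uniform chloride load) to a target curve by least squares,
and `fit_ih_input_resistance()` bisects a global h-current multiplier to hit
a target somatic input resistance.

## Numerical scheme

Each step is operator-split in a fixed order: (1) explicit Euler updates of
the Hodgkin-Huxley gates (clipped to [0, 1], since explicit Euler can
overshoot for fast gates at 0.02 ms) and of the NKCC1 carrier fraction;
(2) implicit Euler updates of the three Markov schemes, solving
`(I - dt Q^T) p' = p` per compartment — the matrix is an M-matrix, so
occupancies stay nonnegative and the update is unconditionally stable
(verified at 50 times the production step); (3) an implicit linear solve for
the voltage with channel conductances at their updated states and
transporter/exchanger currents held at their explicitly evaluated values;
(4) concentration updates from the per-ion membrane currents evaluated at
the *new* voltage — which makes the charge--concentration bookkeeping exact
by construction — followed by glial buffering and longitudinal diffusion.
Voltage clamp replaces clamped rows of the cable system exactly (no series
conductance), and the electrode current is reported from the full current
balance of the clamped compartment.

The compiled engine (Rcpp) and a pure-R reference stepper composed from the
exported module functions implement the identical scheme; a test drives both
through stimulus steps and requires agreement at machine precision. Halving
`dt` moves the peak stimulus response by about 0.01% on the test fixture.

Degenerate inputs fail loudly: non-positive radii, cyclic or disconnected
SWC files, occupancies off the simplex, concentrations driven non-positive
(named compartment and ion), and non-finite voltages all raise errors rather
than propagating.

Spikes are detected as upward crossings of 0 mV with a 2 ms refractory
period.

## Synthetic fixtures and what they do (and do not) show

All tests run on synthetic morphologies: single compartments, ball-and-stick
cables, small branched trees, and a reduced CA1-like cell (`"pyramidal"`:
soma, a tapering 400 µm apical trunk bearing thin oblique branches, tuft,
two basal dendrites, and an axon initial segment plus cable — 42
compartments). The CA1 fixture populates every synapse-density layer, and its
thin proximal obliques play the role that the profuse thin radiatum branches
play in a real reconstruction: small-volume, high-density chloride loaders.

On this fixture the full phenomenology emerges without tuning against it:
HFS (40 transmitter pulses at 100 Hz, 1 mM for 1 ms, 0.1 ms decay, 80%
activation of the somatic and apical synapses) produces ~-7 mV of fast
hyperpolarization followed by a slow depolarization; dendritic `E_GABA`
rises tens of mV above the somatic value; peak chloride load is larger in
smaller-radius compartments; 60% GABA~A~ block preserves the
hyperpolarization while cutting the depolarization several-fold and slowing
the hyperpolarization-to-depolarization switch; KCC2 block raises and
prolongs the `E_GABA` depolarization while shrinking the dendritic K^+^
transient; a secondary pulse excites from the distal dendrites but inhibits
from the perisomatic region; and during the train the dendritic membrane is
shunted to a few percent of its baseline resistance.

What the reduced fixture does *not* reproduce quantitatively: with ~30 times
less dendritic membrane than a full reconstruction, the somatic
depolarization is a few mV rather than tens, so the spontaneous spike burst
riding it is small; the basal-input facilitation *during* the train (as
opposed to after it) does not appear, because the fixture's somatic shunt
outweighs its modest mid-train depolarization; and absolute quantities that
scale with total membrane (pump maxima, input resistance, firing rate at a
fixed current) are properties of the fixture, not of CA1. Passing tests
therefore demonstrate the mechanisms and their couplings, not quantitative
agreement with any particular reconstructed cell.

## Parameter provenance and open choices

Kinetic constants the source field treats as citable building blocks
(channel gating, receptor rates, carrier affinities, pump forms, buffering)
are shipped as an editable YAML file
(`system.file("extdata", "default_parameters.yaml", package = "ionshift")`)
with literature-style values chosen for this package; the engine treats them
as data. Choices worth calling out, with the reasoning:

* **Soma representation**: SWC soma points collapse to one equivalent-area
  cylinder; a single point becomes a sphere-equivalent cylinder (`L = 2r`).
* **Region boundaries**: proximal apical < 150 µm, medial thick radiatum to
  300 µm (radius above 0.6 µm), distal/thin radiatum to 400 µm,
  lacunosum-moleculare beyond; proximal oriens < 100 µm. All are
  configuration values, since the density table names layers, not
  coordinates.
* **KCC2 placement**: somatodendritic only; the axon carries neither KCC2
  nor NKCC1 loading (consistent with KCC2's somatodendritic localization,
  and required for a feasible axonal potassium balance).
* **Pump margin semantics**: the printed somatic pump maximum is treated as
  the post-margin value; the margin itself is the configurable 20%.
* **Receptor desensitization topology**: one slow desensitized state off the
  singly bound state and one fast state off the doubly bound state; rates
  chosen so a 40-pulse, 100 Hz train retains most of its per-pulse charge
  (strongly absorbing desensitization would silence the train's later pulses
  and with them the chloride load).
* **"X% activation"** of synapses is implemented as scaling every synapse's
  conductance by X/100 — deterministic, hence reproducible — rather than
  activating a random subset.
* **Potassium clamp semantics**: `k_clamp = TRUE` freezes every shell at the
  resting value after each step; a waveform clamp interpolates linearly. The
  `kcc2_frozen_k` intervention feeds KCC2 the resting `[K]o` while every
  other mechanism sees the true value.
* **Second-HFS phases**: "falling phase" is the time of 25% decay from the
  depolarization peak; "recovered" is somatic voltage back within 1 mV of
  rest.
* **Noisy drive and glutamate**: the noisy current is Gaussian white noise
  per time step with a recorded seed; glutamate pulses are double-exponential
  conductances (0.5/2 ms, 0 mV reversal, attributed half to Na^+^ and half
  to K^+^), with the total pulse conductance split across the target region
  and sized so the baseline spike probability is below 50%.
* **Glial buffering**: total buffer 500 mM (shell units), rates set so the
  buffer is half-occupied at rest and a +4 mM step relaxes on a ~1 s
  timescale.
* **Problem sizes**: the test suite and the acceptance script use the
  42-compartment fixture, 1-5 s simulations, and 8-12 trials per
  spike-probability condition — sizes chosen so the whole suite documents
  the full protocol battery while remaining a desk-scale computation.

## Limitations

No dendritic spines, extracellular tortuosity, osmotic volume changes, pH
coupling of the fixed bicarbonate pool, GABA~B~ receptors, ClC-2 channels,
transmitter diffusion/spillover, temperature (Q10) scaling, or network
interactions. Calcium has no explicit intracellular buffer beyond the pump
and exchanger. These are deliberate scope boundaries, not oversights.
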