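---
title: "Methods: network-free particle simulation of the Ca2+/CaM/CaMKII system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-free particle simulation of the Ca2+/CaM/CaMKII system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holosim)
```

## The problem

CaMKII is a ring-shaped holoenzyme of 6-12 subunits; each subunit binds
calmodulin (CaM) and can be phosphorylated at Thr286 by its directional ring
neighbour. CaM itself has two lobes with two cooperative Ca2+ sites each, so
a single CaM has 9 lobe states, and a subunit carrying a CaM in any of those
states (times phosphorylation, times context) has ~20 effective states. A
6-subunit ring over 20 subunit states has

```{r}
necklace_count(6, 20)
```

rotationally distinct species (`(1/n) * sum_{d|n} phi(d) k^{n/d}` by
Burnside's lemma). Expanding that network into explicit species and
reactions, as ODE or conventional stochastic simulators require, is
hopeless. `holosim` instead keeps molecules as particles with *binary site
vectors* and stores reaction rules in a lookup table keyed by reactant types
and the states of the sites any rule examines. When two particles collide,
the engine reads off the matching rules; nothing is ever expanded.

## The simulation algorithm

One fixed time step `dt` performs, in order:

1. **Influx** — ions scheduled for this step appear at the source point
   (top-face centre, displaced 1 nm into the volume).
2. **Diffusion** — every free mobile particle takes an isotropic Gaussian
   step with per-axis sd `sqrt(2 D dt)`. Bound clusters move rigidly using
   the *minimum* D among their members (the largest molecule dictates
   transport), and clusters containing an immobilized member (a ring
   subunit) do not move. Bound molecules are co-located: a Ca2+ bound to CaM
   sits exactly on the CaM, a CaM bound to a subunit sits on the subunit.
3. **Boundaries** — reflective faces mirror positions (exact for free
   diffusion), periodic faces wrap, and partially absorbing faces remove
   listed free species with the configured per-crossing probability;
   transient within-step crossings are handled with the Brownian-bridge
   crossing probability `exp(-x0*x1/(D dt))`, which reproduces the
   analytical absorbing half-space flux within a few percent (see the
   boundary test).
4. **Bimolecular reactions** — collision detection uses per-type uniform
   cell grids (cells at least twice the largest binding radius, so an octant
   of 8 cells suffices per probe); for each colliding pair the
   condition-signature lookup returns the candidate rules, the *combined*
   forward rate `kf3 = kf1 + kf2 + ...` fixes the binding radius, and a
   uniform draw partitioned proportionally to the `kf_i` selects the branch.
   Pairs are processed in randomized order and a particle reacts at most
   once per step.
5. **First-order reactions** — per particle, matching flag/unbinding rules
   fire with `p = 1 - exp(-k dt)`; unbinding separates the freed partner
   along a random direction at the unbinding radius.

Reactions never delete particles; they only change site bits, bonds and
positions, which is what makes the reaction *history* of every molecule
traceable.

### Binding radii

A second-order rule fires whenever a pair ends a step closer than its
binding radius. The radius that makes this algorithm reproduce a mass-action
`k_on` depends on `k_on`, `dt` and the mutual diffusion coefficient; it is
found by numerically inverting the reduced-rate relation: the steady-state
absorbed flux of the diffusion-and-absorb iteration is computed on a radial
grid (dimensionless form `k' dt = sigma^3 f(s/sigma)`, `s = sqrt(2 D dt)`),
then `sigma` is root-solved so the realised rate equals the requested one.
The two limits are built-in checks: `f -> 4*pi/3 * (s/sigma)^0` per-step
swept volume for `s >> sigma`, and the Smoluchowski rate `4 pi sigma D` for
`s -> 0`. A well-mixed two-species simulation at the calibrated radius
reproduces the analytic mass-action decay within the Monte-Carlo error of a
few hundred particles (about 2%).

All reactions in the shipped networks are strongly activation-limited
(`1/k_on = 1/k_enc + 1/k_a` with `k_a/k_on` close to 1 at a 5 nm encounter
radius, also at halved diffusion), which is why well-mixed ODE and SSA
oracles are valid comparators:

```{r}
head(regime_report(build_preset("model1_scaled")$model), 4)
```

### Numerical choices

* `dt` defaults to 1 us. `check_timestep()` enforces `k*dt <= 0.1` and an
  rms step no larger than a tenth of the smallest box dimension; halving
  `dt` moves equilibrium counts by less than the Monte-Carlo error (tested).
* Unbinding radius = binding radius of the forward rule, along a uniformly
  random direction. Geminate recombination is not specially tuned; in the
  activation-limited regime the re-encounter probability is small.
* Ties in branch selection cannot occur (the uniform draw is continuous);
  candidate rules are ordered by label for reproducibility.
* One seeded RNG stream drives channel gating, influx, diffusion and
  reaction draws, so a single integer seed fixes an entire run bit-exactly.
  Normal increments use a ziggurat sampler fed by the same stream.
* For pulsed protocols, `simulate_pulsed()` uses a fine step during and
  shortly after each pulse and a coarser step between pulses, recalibrating
  binding radii per step size. Between pulses the tracked ion is essentially
  cleared, and the remaining dynamics (first-order transitions, free
  diffusion with mirror reflection) are step-insensitive. During active
  windows of the desk-scale reduced preset the rms Ca2+ step is about an
  eighth of the lateral box dimension - a deliberate compromise, acceptable
  because reflection is exact and binding radii are calibrated per step.

## The model family

`camkii_molecules()` declares Ca2+ (D = 2.2e-6 cm^2/s), CaM (four Ca2+
sites N1, N2, C1, C2 plus a subunit-binding site; D = 1.0e-7 cm^2/s, an
assumed cytoplasmic value) and the immobilized subunit K (CaM site +
phosphorylation flag). Within each CaM lobe binding is sequential
(cooperative); the lobes are independent.

### Rate constants

The study this package re-implements references a parameter table that is
not part of the main text, so the shipped `default_rates()` are
literature-informed defaults with an explicit construction:

* free CaM: fast, low-affinity N lobe (`kon` 100/150 uM^-1 s^-1, Kd 10/5
  uM), slow, high-affinity C lobe (`kon` 5/10, Kd 2/1 uM);
* thermodynamic linkage: Ca2+ affinity per occupied site is `g_K = 5` times
  higher on subunit-bound CaM and `g_Kp = 25` times higher on
  phosphorylated-subunit-bound CaM; consequently CaM-subunit dissociation
  scales as `Kd0 / g^(x+y)` (`Kd0 = 100` uM for apoCaM), which yields
  trapping on phosphorylated subunits (sub-nM for fully loaded CaM) without
  any hand-tuned trapped rate;
* per-state autophosphorylation rates rise with Ca2+ load and are symmetric
  in the two lobes, so the restricted schemes compare at matched rates.

The construction guarantees microscopic reversibility;
`check_reversibility()` audits every thermodynamic cycle of the expanded
network (product of equilibrium constants = 1 within 1e-6) and flags any
edited rate that breaks a loop. All values live in
`inst/extdata/rates_default.yaml`, so a measured table can be dropped in.
Quantities that depend on the unpublished values (absolute phosphorylation
counts, the exact equilibrium bound-CaM count, the influx level at which the
frequency preference reverses) are reported, not asserted.

### Presets

`list_presets()` enumerates ready-to-run configurations: the Ca2+-CaM test
box (3000 ions + 700 CaM in a 500 nm cube), the saturated-ring
phosphorylation test, the closed full network, the driven prototype (1 x 1 x
2 um box, 6020 CaM, 2006 six-subunit rings, theta-burst channel influx,
bottom face partially absorbing to Ca2+ only), the reduced monomeric network
for the frequency-reversal analysis, the restricted phosphorylation schemes
and the ring-radius sweep. Each has a desk-scale counterpart (volume and
counts scaled at fixed concentrations; the reduced preset keeps the full box
depth and shrinks the lateral dimensions, preserving the ion's diffusive
escape time) so validation runs finish in minutes on one CPU. Problem sizes
used by the test suite: the Ca2+-CaM box at 1/8 volume (375 ions, 88 CaM, 50
ms, 10 seeds), rings totalling 600 subunits, the reduced network at 1/10
volume.

Resting intracellular Ca2+ is omitted from initial conditions (its effect is
minor at these scales); CaM and subunit counts are conserved exactly, and
the Ca2+ ledger (initial + influx - absorbed - cleared = current) must
balance to zero in every run - an invariant, not a tolerance.

## Channels and influx

Channel gating is a two-state Hodgkin-Huxley chain with
`n_inf = 1/(1+exp(-(V+15)/8))` and
`tau_n = 0.06 + 0.7425/(exp(0.55 u/8) + exp(-0.45 u/8))` ms (`u = V+15`),
driven per step by `P(open) = 1 - exp(-n_inf/tau_n dt)` and its complement.
The single-channel current is the offset-exponential expression
`i_ca = -g (V-Vs) e^{-u'}/(1-e^{-u'})` (`u' = (V-Vs)/12 mV`, `g = 5` pS),
with `N` and `Vs` obtained by fitting `N * i_ca` to the GHK current of a 1
um^2 patch:

```{r}
fit_channel_number()[c("N", "V_s", "N_free")]
```

Two details matter. First, the unconstrained least-squares fit is
degenerate: with `[Ca]in` negligible the GHK curve is shape-identical to
`i_ca` at `Vs ~ 0`, so a real-valued `N` lands between integers. Fitting
with `N` constrained to an integer (offset profiled per candidate) selects
`N = 16` decisively. Second, the fitted offset depends on the voltage range:
-60..40 mV gives about -1.3 mV, -80..60 about -1.6, and the shipped default
-100..50 mV (resting hyperpolarization to spike peak) gives -1.91 mV; `N` is
stable across all of these. Ions per open channel and step are
`|i_ca| dt/(2e)` with stochastic rounding, so the expected influx is exact.

Voltage traces are synthetic theta-burst trains (5 spikes at 100 Hz, 5
bursts at 5 or 10 Hz, biexponential spike template from -65 to +30 mV, ~2 ms
wide) - a stereotyped stand-in for a compartmental-model soma recording, not
a reproduction of one. Matched influx pairs are selected from an ensemble of
stochastic trials as the cross-frequency pair with the closest totals.

## Oracles

Three independent references validate the engine:

* **ODE**: `expand_network()` + `ode_trajectories()` expand small rule sets
  into explicit mass-action systems (guarded at 1e4 species - the explosion
  the engine exists to avoid) and integrate them stiffly with moiety
  conservation checked to 1e-8.
* **SSA**: `ssa_simulate()` is an exact well-mixed Gillespie sampler that
  reuses the *same* compiled rule tables without positions (propensities are
  per-rule products of incrementally maintained match-set counts), i.e. it
  is network-free too. The original study compared against a spatial
  Gillespie implementation; a well-mixed sampler is substituted here, which
  is a valid comparator precisely because the tested regimes are
  activation-limited.
* **Exact ring Markov chain**: under saturating CaM with the
  no-phosphorylated-kinase rule, phosphorylation is a directed jamming
  process; `ring_phospho_steady_fraction()` computes the exact expected
  final fraction by dynamic programming over the 2^n ring states (1/2 for
  dimers, 2/3 for trimers, approaching `1 - 1/e`; note the approach is
  *non-monotone* - the trimer value already overshoots the limit).

## Reaction-history analysis

Because particles persist, the event log is a complete record.
`accumulate_edges()` bins events (10 ms default), nets unbindings against
bindings, and accumulates; `classify_edge()` assigns each edge to Layer 1
(free-CaM reactions, including CaM-subunit binding) or Layer 2
(subunit-bound-CaM reactions, including phosphorylation);
`preferred_path()` walks the network greedily along the largest final
cumulative net flux, reporting ties rather than breaking them. The
structural check tying it all together is the ledger identity: for every
vertex, initial count + inflow nets - outflow nets equals the recorded count
at every bin boundary, exactly. Multi-trial series are summed.

Under moderate influx with the shipped rates the walk from apoCaM proceeds
C1 -> C2 -> subunit binding (the C lobe is the high-affinity one, the N
lobe merely the fast one), entering Layer 2 from N0C2; under saturating
influx Ca2+ loading of the N lobe outcompetes subunit binding and CaM tends
to load fully before binding - the pathway deviation that reverses the
frequency preference.

## Frequency dependence and its reversal

The reduced monomeric network (C-lobe loading, one N step, subunit binding,
phosphorylation at 1/s while CaM-N1C2 is bound) reproduces the qualitative
phenomenon: at low per-pulse influx, 10 Hz bursts phosphorylate more than
5 Hz (temporal summation through C-lobe retention); as the per-pulse influx
grows the advantage shrinks monotonically and eventually reverses once
apoCaM is depleted within a burst train. With the shipped default rates the
reversal occurs at roughly twice the per-pulse influx at which the original
study's (unpublished) parameters place it; the influx axis maps through the
rate set, so the test suite asserts the *existence and monotonicity* of the
crossover over an extended influx grid rather than its absolute location.
Well-mixed runs of the reduced preset use a first-order Ca2+ clearance whose
rate is the inverse diffusive escape time of the box depth
(`2 D / Lz^2`), standing in for the absorbing bottom face of spatial runs.

## What passing tests do and do not show

The synthetic models emulate: mass-action kinetics in dilute solution,
hard-walled boxes with idealized boundaries, point-source influx,
stereotyped spike waveforms, and a rate set constructed - not measured. They
do not emulate: crowding and excluded volume, Ca2+ buffers and competing
CaM-binding proteins, Thr305/306 capping, subunit exchange, or
diffusion-limited kinetics (explicitly out of scope). Agreement with the
oracles validates the *simulator*; conclusions about real dendritic spines
inherit every one of the modelling assumptions above.

## Known limitations

* Identical reactant types in one rule (homodimerization) are unsupported.
* Ring complexes are immobilized; mobile holoenzymes would need rigid-body
  ring diffusion.
* The neighbour-spacing convention ("spacing equals radius") is exact only
  for 6-subunit rings; the radius sweep keeps it by construction.
* The well-mixed SSA oracle cannot reproduce nanodomain effects; it is a
  comparator for activation-limited, well-mixed-like conditions only.
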