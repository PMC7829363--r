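---
title: "A topological model of hippocampal spatial learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A topological model of hippocampal spatial learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topomap)
```

## The model

Hippocampal place cells fire in restricted regions of a navigated
environment — their place fields. Because the fields of a large ensemble
cover the environment, the pattern of *coactivity* among place cells encodes
which regions overlap, and hence, by the nerve (Alexandrov–Čech) construction,
the topology of the environment: components, holes, and higher-order
cavities. `topomap` implements this reading end to end:

1. **Environment and behaviour** (`make_environment()`,
   `simulate_trajectory()`): a planar arena minus rectangular or disc
   obstacles, explored by a momentum-smoothed random walk.
2. **Place-cell spiking** (`sample_place_field_map()`,
   `generate_spike_trains()`): Gaussian place fields with log-normally
   distributed sizes and peak rates, driving inhomogeneous Poisson spiking,
   optionally modulated by an 8 Hz theta rhythm with phase precession and a
   60 Hz gamma rhythm through a Boltzmann factor `exp(-A_gamma(t)/tau)`.
3. **Coactivity complexes** (`detect_coactivity_events()`,
   `build_coactivity_graph()`, `build_filtered_complex()`): cells that fire
   within a shared coactivity window `w` (~200 ms) form events; pairwise
   events form a coactivity graph whose cliques are read as simplexes of a
   cell-assembly ("clique") complex, each stamped with its first-appearance
   time `t_sigma`.
4. **Homology** (`betti_numbers()`, `persistence_barcode()`,
   `learning_time()`): simplicial homology over GF(2), computed by
   boundary-matrix reduction; persistence over the first-appearance
   filtration yields the timeline of topological defects and the learning
   time `T_min` — the earliest moment after which the low Betti numbers
   `(b0, b1)` equal the environment's and stay equal.
5. **Flickering complexes** (`evolve_flicker_timeline()`,
   `betti_time_series()`, `lifetime_statistics()`, `stability_summary()`):
   transient networks in which links decay after activation, with
   exponential, quenched (fixed-lifetime), windowed, and randomised-control
   dynamics.
6. **Experiments** (`run_learning_session()`, `run_window_scan()`,
   `run_synaptic_scan()`, `run_learning_region_scan()`,
   `run_additivity_experiment()`): parameter-scan drivers. Statistical
   replicates randomise place-field maps over a *fixed* trajectory, which is
   the efficient way to vary the ensemble while holding behaviour constant.

## Canonical study conditions

Unless stated otherwise, simulated experiments use a 150 × 150 cm arena with
a central 60 × 60 cm square hole (reference Betti numbers `(1, 1)`), a 25-min
session at `dt = 10` ms, speeds with mean 20 cm/s and SD 8 cm/s, and the
ensemble `(s, f, N) = (23 cm, 28 Hz, 350 cells)` with spread coefficients
`a = b = 0.3`. Windows are consecutive 200-ms bins. Theta modulation is on
for flicker experiments (it is the physiological regime and reproduces the
characteristic ~30 s link-reactivation interval); gamma is off except where
gamma is the object of study.

The hole size is our choice for the standard "1.5 × 1.5 m arena with a
hole" setting. A hole must be *resolvable* by the place-field
cover — clearly larger than the largest common field diameter, which for the
log-normal size distribution at `s = 23`, `b = 0.3` reaches ~55–60 cm. A
smaller hole is bridged by the upper tail of the field-size distribution and
its loop is eventually filled, which would contradict the premise that this
ensemble can learn the arena.

## Design choices in detail

**Field-size convention and compact support.** `s_i` is the diameter at
which the Gaussian tuning curve falls to 0.2 of its peak
(`sigma = s_i / (2 sqrt(2 ln 5))`). Fields have compact support: the rate is
truncated at the 5%-of-peak contour (2.45 SD, `field_cutoff`), reflecting
the operational definition of a place field as the region where the cell
fires. This matters: with infinite Gaussian tails, rare tail-coincidence
spiking between cells with disjoint fields accumulates permanent spurious
links in the (ever-growing) coactivity complex, which bridge the hole and
destroy `b1` well within a session. Set `field_cutoff = Inf` for the pure
Gaussian.

**Trajectory model.** Speed follows an Ornstein–Uhlenbeck process reflected
at zero (relaxation 0.5 /s); the heading diffuses at 2 rad/sqrt(s); walls
and hole boundaries reflect specularly. Over 25 min the area-normalised
occupancy CV on a 10 × 10 grid is ~0.3–0.7 — no favoured subregion.

**Theta precession.** The preferred phase advances linearly from 2π at field
entry to 0 at exit, measured along the instantaneous heading; spiking is
modulated by a raised cosine of the phase offset (exponent
`theta_sharpness`, default 1), so the factor lies in `[0, 1]` and the rate
never exceeds `f_i`. Because the factor has mean 1/2, switching theta on
halves the mean rate; comparisons that isolate the effect of phase
*structure* therefore use a rate-matched control (theta off with peak rates
halved). A caveat worth stating plainly: in a purely rate-modulated Poisson
model, precession assigns *offset* preferred phases to cells displaced along
the running direction (this is what makes theta sequences), so the pairwise
coincidence boost of phase alignment averages out across cell pairs — for
windows at or above one theta cycle the phase structure neither helps nor
hurts once rates are matched, and without matching the decimation dominates.
Reproducing a net theta benefit for learning appears to require spike-level
temporal patterning (bursts within cycles) beyond rate modulation.

**Gamma coupling.** `A_gamma(t) = (1 + cos(2 pi f_gamma t)) / 2`, normalised
to `[0, 1]`; the Boltzmann factor `exp(-A_gamma/tau)` concentrates spikes at
gamma troughs. `tau = Inf` (the "infinitely hot" limit) disables coupling;
the physiological default is the mean amplitude, `tau = 0.5`.

**Flicker decay is a lease, not a memoryless hazard.** Each (re)activation
grants the link an independent `Exp(tau)` lifetime; the link is present
while any lease is unexpired. Survival measured from the last activation is
then `~exp(-t/tau)`, but reactivation can only extend life. We chose this
over a plain memoryless hazard because a constant hazard makes birth-to-death
spans exactly `Exp(tau)` no matter how often a link reactivates — it cannot
produce effective lifetimes longer than `tau`, a survivor pool, or any
stabilising effect of the exponential tail, all of which characterise the
intended dynamics. Under the lease model, regularly reactivated links
acquire effective lifetimes `tau_e(2) ~ 2-3 tau` and a survivor core forms,
while triangles (which need all three links alive) live shorter than single
links. The quenched variant (fixed lifetime `tau` from the last activation)
lacks the tail and flickers more, and `tau = Inf` recovers the perennial
growing complex in every decaying mode.

**Homology engine.** Coefficients are GF(2) throughout. Betti numbers come
from sparse Gaussian elimination of the boundary matrices; persistence from
the standard column-reduction with the clearing (twist) optimisation, both
in compiled code. Equal-time simplexes are ordered by dimension, then
lexicographically — any tie order within a filtration step yields the same
interval multiset. Zero-length intervals are dropped. The two routes (direct
rank vs interval counts) are cross-checked on random filtrations in the test
suite. The learning criterion for planar environments gates on `(b0, b1)`
only; complexes are dimension-capped at `d_max = 2` for scans (triangles
suffice to fill 1-cycles) and `d_max = 3` when `b2` is of interest.

**Synapses.** Transmission and readout-response probabilities are drawn once
per (assembly, link) and per assembly from Gaussians with modes `p*`, `q*`
truncated to `[0, 1]`; an event survives if at least one assembly containing
its pair transmits and responds. The identity limit (`p* = q* = 1`,
zero spread) is exact.

## What the generator emulates — and what it does not

The synthetic trajectories emulate non-preferential exploration at rodent
speeds; they have no goal-directed structure, no wall-following bias, no
immobility bouts, and no theta-speed coupling. Spiking is Poisson given the
rate — no bursting, refractoriness, or experience-dependent plasticity; the
two rhythms are pure sinusoids. Place fields are unimodal and static.
Passing tests therefore certify the model's internal logic (topological
machinery, parameter dependencies, stability phenomena), not the full
statistics of recorded hippocampal data.

## Problem sizes used by the checks

The automated checks run the canonical 25-min session at `(23, 28, 350)`;
the coactivity-window scan uses a single 90-min session with windows between
62.5 and 250 ms (one map per width); the synaptic scan reuses one session's
events across the probability grid; flicker stability series are evaluated
at 10–20 time points. These sizes were chosen so each check completes in
minutes on a single core while leaving the measured quantities' estimators
within their stated tolerance bands.

## Known limitations

* Learning times in the canonical arena are ~15–20 min at `w = 200` ms, in
  line with the power-law scaling `T_min ~ w^-1.2` anchored at
  `T_min(25 ms) ~ 5 h`. Flicker-stability thresholds scale with the
  environment's `T_min` (complete suppression of fluctuations appears at
  `tau* ~ 0.5-0.6 T_min`); absolute thresholds quoted for faster-learned
  (smaller) environments are correspondingly smaller than ours.
* With theta on at `w >= 1` theta period, rate decimation outweighs
  synchronisation unless rates are matched (above); the gamma Boltzmann
  factor, by contrast, does concentrate coincidences (its amplitude is
  shared by all cells) and measurably helps at sub-gamma-period windows
  under a rate-matched control.
* In the windowed (finite-latency) mode the per-window complex contains
  only cells active within the window; in the decaying modes vertices
  persist once born, so a cell whose links have all decayed counts as an
  isolated component of `F_tau(t)`.
* The windowed (finite-latency) mode evaluates on a `delta_varpi` grid of at
  least `0.01 * varpi`; sub-grid flickers are invisible by construction.
* Zigzag-style interval decompositions of flickering complexes are not
  computed; stability claims are made on the per-step Betti series, which is
  what the statements concern.
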