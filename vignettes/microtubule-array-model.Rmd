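---
title: "The mtarray model: assumptions, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mtarray model: assumptions, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtarray)
```

## The model

`mtarray` simulates an array of microtubules (MTs) undergoing dynamic
instability inside a confined cell, coarse-grained at the whole-filament
level: an MT is a straight element of continuous length anchored at a
central nucleation site, with no protofilament, GTP-cap or bending
detail. Six assumptions define the system:

1. A fixed pool of nucleation sites (default 500) caps the MT number; a
   site whose MT depolymerizes completely re-opens and is eligible for
   nucleation at the next step.
2. MTs stay anchored until complete depolymerization and grow as straight
   radii.
3. Growth velocity is linear in free tubulin:
   `v_g = k_on [Tub]_free + C1` with `k_on = 0.0167` µm µM⁻¹ s⁻¹ and
   `C1 = 0`.
4. Shortening velocity and the catastrophe/rescue frequencies do not
   depend on tubulin concentration.
5. Depolymerized tubulin is instantly competent to re-polymerize (no
   GDP→GTP recycling delay).
6. A tip reaching the cell boundary undergoes a forced catastrophe.

Tubulin is closed under an exact mass balance. Lengths convert to
concentration through the lattice packing constant (1624 dimers per µm)
and the unit bridge 602.214 molecules per µM·µm³; the free pool is always
*derived* as budget minus polymer, never integrated independently, so
conservation is structural and holds to rounding error at every step
(verified to 1e-9 relative in the test suite).

## Parameters

| parameter | units | default | role |
|---|---|---|---|
| `n_sites` | – | 500 | nucleation sites = max MT count |
| `rate_per_site` | s⁻¹ | 0.0005 | per-site nucleation rate |
| `total_tubulin` | µM | 35 | tubulin budget |
| `radius`, `height` | µm | 25, 0.5 | cell cylinder |
| `volume` | µm³ | π·r²·h ≈ 982 | cytoplasmic volume (see below) |
| `k_on`, `c1` | µm µM⁻¹ s⁻¹, µm s⁻¹ | 0.0167, 0 | growth law |
| `v_g, v_s, k_c, k_r` | µm/s, µm/s, s⁻¹, s⁻¹ | preset | plus-end dynamics |
| `dt` | s | 1 | step duration |

Three presets carry plus-end parameters measured in LLCPK1 epithelial
cells: two interphase sets — `setA` (low catastrophe 0.026 s⁻¹, high
rescue 0.175 s⁻¹, producing a near-saturated, very stable array) and
`setB` (2-fold more catastrophe, 2-fold less rescue, a more dynamic
array) — and `nebd`, the prophase measurement around nuclear envelope
breakdown (3-fold more catastrophe and 7.5-fold less rescue than Set A),
which dissolves an interphase array within minutes of simulated time.

**Cell volume.** The thin-cylinder cell is usually quoted as
"approximately 1000 µm³"; the exact cylinder volume is
π·25²·0.5 ≈ 981.75 µm³. We default to the derived value: it is the
physically consistent choice (it scales correctly if the radius or height
is changed), and at the standard parameterization it reproduces the
reference Set B steady state slightly better than the rounded 1000
(the acceptance suite quantifies this). Any volume can be passed to
`cell_geometry()` explicitly.

## The step algorithm and its conventions

Each step of `simulate_mt_array()` executes, over all sites: boundary
jitter draw → growth-velocity evaluation → nucleation of empty sites →
growth/boundary/catastrophe for growing MTs → shortening/
removal/rescue for shortening MTs → one batch reconciliation of the free
pool. Where the coarse discrete-time scheme admits more than one reading,
the following conventions are fixed:

- **Rate → probability.** Per-step event probabilities are
  `1 − exp(−k·dt)`, the exact probability that a Poisson process fires
  at least once in a step. At the default magnitudes (k ≤ 0.175 s⁻¹,
  dt = 1 s) this differs from the naive `k·dt` by under 1%, and it stays
  a valid probability for any rate or `dt`. Users attempting exact
  matches against codes using the linear convention should expect
  percent-level differences in transition statistics — and, because
  complete depolymerization of a boundary-length MT is a rare
  large-deviation event, potentially much larger relative differences in
  quantities driven by such rare events (site turnover times, slow decay
  half-times).
- **Move-then-test.** An MT moves according to its current phase, then
  tests its stochastic transition; a new phase acts on the *next* step.
  Applied uniformly, this keeps every site's update independent within a
  step.
- **Synchronous pool coupling.** All MTs in a step share the growth
  velocity computed from the start-of-step free pool, and the pool is
  reconciled once at step end. Results are therefore independent of site
  iteration order. (Per-step uptake is at most ~2% of the free pool at
  defaults, so the batch update cannot overdraw it.)
- **First increment.** A newly nucleated MT takes its first step at the
  parameter set's *mean* growth velocity (growth must initiate even if
  transiently computed velocity were zero) and is concentration-dependent
  thereafter; it is not catastrophe-tested in its nucleation step.
- **Boundary.** A growing tip that would meet or exceed the (possibly
  jittered) boundary is clamped exactly to it and switched to shortening;
  there is no sub-step partial advance. If a jittered boundary falls
  inside an existing MT, that MT is likewise clamped and shortening.
- **Dilution semantics.** `apply_dilution()` (or a stage's
  `dilution_factor`) rescales the *budget*; the free pool, derived as
  `max(0, budget − polymer)`, clamps at zero while assembled polymer
  exceeds the reduced budget, and depolymerized tubulin above the budget
  is discarded. This models physical removal of dimers from the
  cytoplasm; crediting all depolymerized mass back to the reduced pool
  would instead permit regrowth.

## Nucleation, zones, noise

**Concentration-dependent nucleation.** Optionally the per-site rate is
`slope × [Tub]_free`, a linear law through the origin. The slope is
user-set; the default (0.0005/7 s⁻¹ µM⁻¹) recovers the measured
interphase rate at the measured ~7 µM interphase free concentration. No
saturation is implemented — whether the linear rise continues above
~8–10 µM free tubulin is experimentally open, so the slope is simply
exposed.

**Two-zone catastrophe.** `zone_spec()` splits the cell at
`radius − peripheral_width`: tips strictly interior experience
`k_c × interior_catastrophe_factor` (default 1/16, the reported
interior stabilization); tips at or beyond the seam, the full measured
frequency. Rescue is uniform, as no regional rescue difference has been
reported. A peripheral width equal to the radius reproduces the unzoned
model exactly (unit-tested).

**Per-step noise.** Measured catastrophe/rescue frequencies often carry
standard deviations comparable to their means, so the noise model draws
`k_c` and `k_r` uniformly on `[0, 2·mean]` — the widest symmetric range
that stays non-negative — and `v_s` uniformly on `[mean − sd, mean + sd]`
(truncated at 0), reading "a range covering one standard deviation" as
±1 sd; ±0.5 sd would also be defensible, but the wider reading was fixed
once and documented. Draws are independent per MT per step — the
variation is attributed to each MT's local environment — while the
boundary jitter (a uniform reduction of the radius by up to
`radius_jitter_max`, default experiment 3 µm) is a single global draw
per step, since there is one cell boundary. Whether the original
formulation drew noise per MT or globally per step is not stated; per-MT
was chosen as the reading consistent with "variations in the dynamic
instability of each MT".

## Analysis definitions

- **Steady-state summary**: time-average within a window (default the
  last 2000 s of an assembly) per replicate, then mean ± sd across
  replicates.
- **Half-time**: first crossing of the midpoint between the
  pre-transition baseline (`series[1]`) and the post-transition
  asymptote, estimated as the mean of the last 10% of samples, with
  linear interpolation between steps. Defined this way because published
  "half time" usage comes without a formula; the asymptote estimate
  matters (for a linear ramp to zero over 400 s it yields 190 s, not
  200 s).
- **Plateau diagnostic**: a series is declared stationary when both the
  rolling mean and the rolling sd change by < 5% between the last two
  non-overlapping windows (default 2000 s). The sd criterion follows
  Oosawa's observation that fluctuation amplitude relaxes more slowly
  than the mean. Note that for strongly autocorrelated series (MT counts
  near saturation) the rolling sd itself is noisy, so this binary
  diagnostic is conservative and seed-sensitive near the threshold.
- **Length histograms**: right-closed 1 µm bins on [0, R], a length of
  exactly R falling in the last bin; and a five-bin histogram of
  `length/R` over [0,0.2), …, [0.8,1], matching how measured tip
  positions are binned as fractions of the cell radius (the open/closed
  convention at the inner edges is fixed here and documented, as the
  measured-data convention is unstated).

## Validation oracles

Two closed-form limits anchor the stochastic engine:

- **Dogterom–Leibler limit.** With the pool pinned (`pinned_free`), the
  boundary removed (`radius = Inf`) and constant parameters in the
  bounded regime (`v_s·k_c > v_g·k_r`), the stationary length
  distribution is exponential with mean `v_g·v_s/(v_s·k_c − v_g·k_r)`.
  The engine's empirical mean matches within Monte Carlo and
  discretization error (a positive bias of order `v·dt` is expected at
  dt = 1 s; the suite checks 10%).
- **Two-state occupancy.** With velocities zeroed, each MT is a two-state
  Markov chain whose growing-phase fraction converges to
  `k_r/(k_c + k_r)`; checked across 4000 independent chains.

Beyond the oracles, the acceptance suite re-runs the canonical staged
experiments — interphase steady states for both parameter sets, the
nucleation-shutoff stability contrast, 10× dilution, the prophase
switch with and without a 5-fold nucleation boost, single-parameter
swaps between the interphase sets (rescue dominates every output, in
both directions), the zone-width scan (monotone MT-count and free-pool
response), and boundary jitter versus parameter noise (jitter shifts the
length distribution and free pool, parameter noise does not).

## Problem sizes

Simulations in the tests and the acceptance script use the standard cell
(500 sites) with 10,000 s assemblies and staged interventions up to
173,000 s, at 4–6 replicate seeds per condition — matching the scale at
which the reference results are defined; the complete suite runs in well
under a minute thanks to the compiled per-step core.

## What the simulator does and does not emulate

The generator reproduces the *modeled* cell: a homogeneous (or two-zone)
disc of cytoplasm, straight non-interacting filaments, first-order
transitions, one shared tubulin pool. Passing tests therefore validate
the bookkeeping, the stochastic kinetics and the staged-protocol
machinery — not biological completeness. Known limitations, deliberate
non-goals: no MT bending, severing, minus-end dynamics or motor
transport; no pause state; no GTP-cap or age/length-dependent
catastrophe (the spatial zone acts as a proxy); 2-D disc geometry only;
centrosome repositioning only as boundary jitter. Rare-event statistics
(slow array-decay half-times, site-turnover counts over many hours)
are exponentially sensitive to the per-step conventions above, so such
quantities should be compared across codes only at generous tolerances.
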