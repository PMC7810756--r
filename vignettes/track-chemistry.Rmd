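---
title: "Methods: stochastic track-segment chemistry of water radiolysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic track-segment chemistry of water radiolysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackchem)
```

## The problem

When an energetic ion traverses liquid water it ionizes and excites water
molecules along its path.  Within about a picosecond the excited and ionized
molecules dissociate into the primary radiolysis products — the hydrated
electron `e_aq-`, the hydroxyl radical `OH`, `H`, `H2`, `H3O+`, `OH-` — and
from 1 ps to about 1 microsecond these species diffuse and annihilate each
other ("the chemical stage").  The quantity of interest is the radiation
chemical yield, the G-value: molecules of a species per 100 eV of absorbed
energy, as a function of time and of the ion's linear energy transfer (LET).
Near the Bragg peak the ionization density is so high that radical–radical
recombination dominates, and the secondary products `O2`, `O2-` (superoxide),
`HO2`, `HO2-` and `O-` — usually negligible at low LET — participate
measurably in the `OH` budget.  This package simulates that chemistry with an
extended reaction scheme carrying those five secondary species, and computes
track-segment yields G′(E) by the split-simulation procedure: yields per
0.25 MeV/u energy step, accumulated into N(E) and differentiated back,
G′ = 100 · dN/dE.

## Model components

**Species registry.**  Twelve point-like species, each with atom counts,
charge and a diffusion coefficient.  The five secondary species carry the
published diffusion coefficients (2.4, 1.75, 2.3, 1.4, 2.0 × 10⁻⁹ m²/s for
`O2`, `O2-`, `HO2`, `HO2-`, `O-`).  The seven base species are not tabulated
in the source for this scheme; we adopt the canonical Frongillo-style values
(`e_aq-` 4.9, `OH` 2.8, `H` 7.0, `H2` 4.8, `H3O+` 9.46, `OH-` 5.3, `H2O2`
2.3), the same literature family the secondary values come from, and they
are overridable through the species file.  Van der Waals radius and mass are
stored as optional metadata only; no implemented equation uses them.

**Reaction network.**  33 reactions: 31 bimolecular plus two pseudo-first-
order reactions with the solvent (`O- + H2O -> OH + OH-` and
`HO2- + H2O -> H2O2 + OH-`, both 1.36 × 10⁶ s⁻¹; water is implicit and not a
tracked particle).  Every entry is validated to conserve charge exactly and
to balance hydrogen and oxygen once a signed integer number of implicit
water molecules is allowed ("No product" entries produce water only and
spawn no particle).

**Encounter radii.**  The stochastic engines need a reaction distance, not a
rate constant.  We invert the Smoluchowski relation k = 4π N_A (D_A + D_B) R
for fully absorbing partners: R = k_pair / (4π (D_A + D_B)) with
k_pair = k / (10³ N_A).  Reactions whose tabulated k lies below the
diffusion limit (e.g. `OH + H2O2` at 2.87 × 10⁷) simply receive a small
radius.  This choice reproduces the tabulated rate constant exactly in the
homogeneous limit — the contract the acceptance suite verifies — at the cost
of compressing all "partially diffusion-controlled" physics into the radius.
A Collins–Kimball (finite surface reactivity) variant was considered and not
implemented: it changes transient pair kinetics but not the homogeneous
rate, and the radius column can be overridden through the reaction file by
users who need a different encounter model.

**Identical-reactant convention.**  The source tables do not state whether k
for `A + A` reactions is defined by d[A]/dt = −2k[A]² or −k[A]².  We default
to the first (the convention of the radiation-chemistry compilations this
scheme derives from) and expose the second as
`reaction_table(aa_convention = "k1")`.  The choice propagates consistently:
it scales the encounter radius, the engines' pair rate and the well-mixed
oracle, so all three always agree with each other.

## The physicochemical stage

Each energy-deposition event is classified as single ionization, A1B1 or
B1A1 excitation, Rydberg/diffuse-band excitation, or dissociative
attachment, and dissociates according to the tabulated branching ratios
(ionization → `H3O+ + OH` plus the ejected electron, probability 1;
A1B1 → `OH + H` 0.65 / relaxation 0.35; B1A1 → `H3O+ + OH + e_aq-` 0.55 /
`OH + OH + H2` 0.15 / relaxation 0.30; Rydberg → 0.5/0.5; attachment →
`OH + OH- + H2`).  Holes are not tracked: ionization yields `H3O+ + OH`
directly, and the ejected electron becomes the hydrated electron at its
thermalization endpoint.

The branching table gives no displacement distances, so placement is a
surrogate with two parameters: the hydrated electron is displaced
isotropically with an exponential radial law of mean 5 nm (a typical
sub-excitation electron thermalization distance), and heavy fragments are
separated by a fixed 0.3 nm (one molecular diameter) along random
directions.  Both are configuration values, flagged as non-published, and
setting them to zero collapses all products onto the event position.

## The synthetic track generator

The physical stage (cross sections, secondary-electron transport) is out of
scope; a parameterized generator stands in for it.  Events are laid along
the ion axis with exponential axial spacings of mean (mean event
energy)/LET, so the linear energy density is LET-consistent by
construction; radial offsets are exponential with a mean that shrinks as the
ion slows (default max(0.5, 2√E) nm), emulating the narrowing penumbra near
the Bragg peak.  Event energies follow a shifted exponential with an 8 eV
floor (the lowest electronic excitation of water) and 40 eV mean; event
types default to proportions {ionization 0.75, A1B1 0.09, B1A1 0.09,
Rydberg 0.05, attachment 0.02}.  Generation stops at the first event pushing
the running total past 10 keV, and segments exceeding 10.1 keV are rejected
and resampled, so every accepted segment deposits 10–10.1 keV — the same
windowing used to keep heavy-ion chemical-stage simulations tractable.

These knob values are honest surrogates: no event-level statistics exist to
calibrate them against.  One visible consequence is that with a 40 eV mean
event energy the 1 ps yields are lower than the classic primary yields of
liquid water (about 2.3 `OH` per 100 eV here versus ~5 in full
track-structure codes, which resolve every ~20 eV ionization).  All relative
and kinetic quantities — decay shapes, LET trends, rate recovery, the
G′ machinery — are unaffected by this overall scale, but absolute G-values
should be read as properties of the stated surrogate world, not as
predictions.  A green test therefore establishes the correctness of the
chemistry and bookkeeping, not agreement with measured absolute yields.

The energy-to-LET mapping is likewise a documented surrogate (a Barkas-style
effective-charge fit, LET = 26 Zeff² E^-0.8 eV/nm with
Zeff = Z(1 − exp(−125 β Z^(−2/3))), flat 0.2 eV/nm for electrons), anchored
to typical proton stopping in water and giving ~690 eV/nm for C at
0.83 MeV/u.  Users with real stopping tables can supply them per ion.

## The chemistry engines

Two engines share one contract (a `chemistry_result` whose counts are
reconstructed exactly from the initial population plus the stoichiometry of
fired reactions — the ledger is the data structure, so the stoichiometric
consistency invariant holds by construction and is additionally verified
against the surviving-molecule tally in the tests).

**Brownian dynamics** steps every molecule with isotropic Gaussian
displacements (per-axis variance 2D·dt).  A pair reacts when it ends a step
inside its encounter radius, or via a Brownian-bridge test — probability
exp(−(d₀−R)(d₁−R)/(D′dt)) of an unobserved crossing during the step.  The
step grows logarithmically (dt = min(10 ns, max(0.1 ps, 0.05 t))), and is
additionally capped so that no reactive pair is likely to diffuse across its
gap in one step (dt ≤ gap²/(C·D′_max), C = 16 by default).  This dynamic cap
matters: the 1D bridge formula is only locally valid, and without the cap
the large late-time steps over-count encounters (we measured a ~15%
overshoot of pair reaction probability at r₀ = 2R with the schedule step
alone; with the cap the two-particle escape probability is correct to
Monte-Carlo error, and BD converges to the IRT result on full tracks as C
increases).  Simultaneous contacts are resolved nearest-partner-first;
products appear at the pair midpoint (bimolecular) or the parent position
(unimolecular).  First-order channels fire with probability 1 − exp(−k dt).
A periodic box (minimum image, cell lists) supports homogeneous validation
runs; track segments run in open space.

**Independent reaction times** samples, once per reactive pair, a reaction
time from the diffusion-controlled first-passage distribution
W(t | r₀, R, D′) = (R/r₀) erfc((r₀−R)/√(4D′t)): the pair ultimately reacts
with probability R/r₀ and the conditional time comes from inverting the
erfc.  The earliest pending event fires; partners of consumed molecules are
invalidated.  When products are created, the stored positions of all
survivors are first propagated to the event time by sampling their free
Green's function (lazy position updates), and the new pairs are sampled from
the updated geometry.  This position propagation is not optional decoration:
with static creation-time positions the cluster never expands and products
systematically over-react (we measured ~30% too few `OH` survivors at 1 μs
on dense carbon tracks); with it, IRT and converged BD agree within
Monte-Carlo error.  The engine ignores Coulomb interactions between charged
pairs (the neutral-pair W is used throughout), like the BD engine.

**Scavengers** act as per-species first-order sinks with capacity k[S]
(s⁻¹); scavenged molecules are logged separately so time-resolved scavenged
yields can emulate probe experiments at the usual scavenging-time ladder
(7, 16, 63, 251, 1000 ns).

## The well-mixed oracle

`integrate_wellmixed()` integrates the full mass-action system with an
adaptive Dormand–Prince 5(4) pair written in R (relative tolerance 10⁻⁸).
The network's rate constants span 8.3 × 10⁵ to 1.13 × 10¹¹, but at the
concentrations the package simulates (≤ millimolar) the fastest
pseudo-first-order rate is ~10⁸ s⁻¹, comfortably inside the stability range
of the adaptive explicit steps; the integrator aborts with a stiffness
diagnostic if its step budget is exhausted rather than returning a wrong
answer.  The oracle shares the engines' A + A convention, which makes it a
genuine cross-check: the uniform-box BD run must land on the oracle
trajectory, and does, within Monte-Carlo error plus a ~5% discretization
allowance.

Homogeneous rate recovery is asserted for the BD engine only: IRT has no
periodic box (its pair-time machinery presumes open space), so its
homogeneous behaviour is validated indirectly — exact two-particle laws plus
track-population agreement with BD.

## Yields and the split simulation

`gvalue()` is the definition G = 100 · count / E_dep.
`simulate_track_yields()` averages G(t) over independent segments and
reports the standard error over tracks; with the reference 1000 tracks the
SEM of G(`OH`) at 1 μs is well under the ~5% statistical error quoted for
this track count.  `integrate_segment_yields()` implements the split
simulation on the 0.25 MeV/u grid; `differentiate_to_gprime()` recovers
G′(E) by central differences (default) or a Hyman-filtered monotone spline —
the published procedure fits an unnamed curve to N(E), so the scheme is an
exposed choice recorded in the output metadata rather than an assertion.
Because the accumulated N(E) is a step-sum, central differences recover the
integrand at half-step offsets; the round-trip is exact for constant G′ and
accurate to the scheme's order otherwise, which is what the acceptance test
asserts.

## Numerical and reproducibility choices

* All randomness flows through R's RNG (including inside the C++ engines),
  so `set.seed()` gives bit-identical runs per engine and version.
* Units are fixed at the interfaces: seconds, nm, eV, MeV/u, eV/nm,
  dm³ mol⁻¹ s⁻¹, 10⁻⁹ m²/s; conversions are internal.
* Ties in the BD nearest-partner resolution have measure zero (continuous
  distances); the candidate sort makes resolution deterministic per seed.
* Outputs are plain TSV with `#` metadata headers (seed, engine,
  configuration hash) via `write_result_tsv()`.

## Known limitations

* Absolute 1 ps yields depend on the surrogate event-energy scale (above).
* No Coulomb drift between charged species; no multi-ionization channels,
  hence no O(³P) chemistry and the known high-LET H2O2 saturation behaviour
  above ~100 eV/nm is outside the model; no nuclear fragmentation.
* IRT carries the classical independent-pairs approximation; residual
  engine differences on very dense tracks are at the few-percent level of
  surviving counts at 1 μs.
* The stopping surrogate is a smooth fit, not measured stopping power; any
  quantitative G′(E) study should supply a real table via
  `ion_spec(stopping = ...)`.
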