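---
title: "Simulating interacting particle systems with sample classes"
author: "latticeIPS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating interacting particle systems with sample classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticeIPS)
```

## The model class

An interacting particle system (IPS) is a continuous-time Markov process
on a finite site graph.  Each site holds at most one particle (volume
exclusion); a site's state is its occupant species or "open" (`0`).
Reactions are *on-site* (a single site changes: death `A -> 0`,
immigration `0 -> A`, transformation `A -> B`) or *pairwise* (a center
site and one adjacent site change together, written positionally:
migration `A + 0 -> 0 + A`, binary fission `A + 0 -> A + A`, predation
`F + R -> F + F`).  Kinetics are mass-action over ordered
(center, neighbor) pairs: a pairwise reaction with rate constant $k$
contributes rate $k$ for every ordered adjacent pair carrying the right
reactants.  A consequence worth flagging: for a symmetric reactant pair
such as `A + A -> B + 0`, each unordered adjacent A–A pair contributes
$2k$, because either particle can serve as the center.

Open sites are not a species, but they participate in reactions — volume
exclusion is why fission needs an adjacent open site at all — and they
may be sampled as reaction centers (immigration).  Higher-order reactions
are rejected at validation; they should be decomposed into pairwise steps
through explicit intermediate complexes, which is a modeling decision,
not a simulator one.

## Channels, sample classes, and exactness

The per-particle rate of a pairwise reaction depends only on the *number*
$j$ of adjacent reactants, not on their arrangement.  Each pairwise
reaction is therefore split into channels $j = 1..D$ with per-particle
rate $jk$, where $D$ is the nominal neighborhood size (4 on the square
lattice, 6 on the hexagonal and face-neighbor cubic lattices); a model
with $P$ pairwise and $O$ on-site reactions yields $R = DP + O$ channels.
Channels that share the ordered reactant pair and $j$ sample from the
same *sample class* — the n-fold-way (Bortz–Kalos–Lebowitz) device — so
there are $C = DU + V$ classes for $U$ unique ordered pairs and $V$
unique on-site reactants, never more than channels.  Class membership is
a function of a site's occupant and its *neighborhood composition*, the
count vector of open sites and species among its neighbors; for degree
$D$ and $L$ species there are $\binom{D+L}{L}$ compositions
(`countConfigs()`, with `compositionRank()`/`compositionUnrank()` the
lexicographic bijection).

The channel propensity is $\lambda_r = (\text{per-particle rate}_r)
\times |\text{class}(r)|$.  The direct method draws
$T = -\log(U_1)/\lambda_0$ and picks the smallest $j$ with
$\sum_{r \le j}\lambda_r \ge U_2\lambda_0$; the firing particle is
uniform in the class, and the partner uniform among the $j$ qualifying
neighbors.  Because class sizes are integers and propensities are always
recomputed as rate × size (never accumulated by deltas), propensities
carry no floating-point drift.

After an event, only the changed sites and their neighbors are touched:
memberships use swap-with-last removal through a position map (O(1) per
class change), so per-event cost scales with the neighborhood, not the
lattice.  The from-scratch *global update* (`rebuildGlobal()`) exists as
the correctness oracle: the test suite asserts bit-level agreement of
occupancy, compositions and memberships (and 1e-9-relative agreement of
propensities) between the incremental state and a full rebuild after
every event of randomized streams through all four packaged models, plus
agreement with an independent plain-R lattice scan and, on tiny graphs,
distributional agreement with the exactly enumerated CTMC
(`enumerateCTMC()`, matrix-exponential law).

## τ-leaping on a lattice

`runTauLeap()` implements fixed-step τ-leaping: per leap, Poisson
$(\lambda_r \tau)$ events per channel, applied *sequentially in uniformly
shuffled order*.  Sequential application is forced by the spatial
non-commutativity of updates; the shuffle removes the bias a fixed
channel order would introduce (a test demonstrates the skip-count
asymmetry of ordered firing on a contrived fission/death conflict).
Events whose sample class is empty when their turn comes are *skipped*
and counted in the trajectory's `skipped` slot; users should shrink τ
when the skip fraction is material.  τ is deliberately a user choice:
adaptive leap-condition selection is out of scope for this version, and
no accuracy guarantee is attached to any particular τ.

## Numerical and design choices

* Uniform draws for the time step are resampled if 0, so
  $\log U$ is defined; the channel rule is strict-left/weak-right, and
  zero-rate channels can never be selected.
* All randomness (including inside the compiled loops) flows through R's
  RNG, so `set.seed()` makes event sequences exactly reproducible across
  platforms; `simulateIPS()` seeds replicate $i$ with `seed + i`.
* Closed boundaries are represented by shorter neighbor lists — no
  padding pseudo-species; boundary sites simply never populate high-$j$
  classes.  Channels exist for $j = 1..D$ regardless, keeping the channel
  table configuration-independent.
* Coordinates: square/cubic lattices use integer $(x, y[, z])$ with von
  Neumann/face neighborhoods; the hexagonal lattice uses axial
  coordinates $(q, r)$ with the six standard axial offsets.  Sites are
  indexed with $x$ varying fastest; file outputs carry 0-based site
  indices plus coordinates, so no consumer needs the internal convention.
  The cubic default is the 6 face neighbors with $D$ overridable, since
  wider 3-D neighborhood conventions (e.g. $D = 8$) leave the algorithm
  unchanged.
* `SimState` has reference semantics (the state lives behind an external
  pointer into compiled code); `rebuildGlobal()` returns an independent
  copy.  `resetState()` reuses allocations inside replicate loops.
* Run configurations are single JSON documents; validation reports the
  offending field path (e.g. `$simulation$t_final`) rather than line
  numbers, which JSON parsing does not preserve.

## The example models and what they demonstrate

Numeric rate constants for the four examples are package defaults chosen
once to reproduce each qualitative phenomenon at desk scale, and every
default is overridable.

* **Predator–prey** (hexagonal, predation 0.3, reproduction 1.0,
  migration 1.0, death 0.2; initial densities R 0.30, F 0.05): sustained
  coexistence through traveling prey patches; with predation set to 0 the
  fox count reduces exactly to a pure death process, giving a closed-form
  check.
* **Rock–paper–scissors** (periodic square, birth 0.6, death 0.05,
  migration 0.4, predation 1.0): three exchangeable species under cyclic
  predation; on small lattices, raising migration mixes the populations
  and shortens the time to first extinction.
* **Immunotherapy** (closed square, barrier ring `B`, central tumor):
  immune influx `B + 0 -> B + I`, two competing kill reactions
  (`I + C -> I + 0` / `I + C -> I + Fb`), and fibrotic porosity modeled
  as a two-step passage through the transient species `FI`
  (`I + Fb -> 0 + FI`, then `FI + 0 -> Fb + I`) — one concrete mechanism
  for "slightly porous", chosen for its locality.  Default rates grow a
  fibrotic shell while the tumor persists behind it.
* **Lipid oxidation** (closed 101×101 square, single oxidized walker at
  the center): one reaction, `Ox + 0 -> Dp + Ox`; deuterated PUFAs (`De`,
  fraction $p$, placed uniformly) are inert by default (optional slow
  oxidation rate `epsilon`).  The depleted-chain length is the `Dp` count
  at absorption.  The square lattice is a declared default — the membrane
  geometry is configurable — and the hop rate only sets the time unit.

## Locating the deuteration threshold

`pufaSweep()` sweeps $p = 0, 0.02, \ldots, 0.40$ with 2000 replicates per
point (a size chosen for estimator stability; the walk itself is cheap).
Mean chain length falls from ≈70 at $p = 0$ to ≈10 at $p = 0.40$.  The
*relative* per-interval decrease of the mean rises with $p$ and saturates
once deuteration-trapping dominates self-trapping; beyond the saturation
point the curve is close to log-linear in $p$.  The raw argmax of
per-interval relative drops is therefore an unstable statistic — on the
plateau it is decided by Monte-Carlo noise even at large replicate
counts.  `deuterationThreshold()` instead fits, by weighted least squares
(weights: inverse squared coefficients of variation), a
decay-rate-saturation model to $\log$ mean length — quadratic in $p$
below a knee $\psi$, linear above, continuous and differentiable at
$\psi$, with the curvature sign constrained so the decay rate cannot fall
with $p$ — and reports the midpoint of the first sweep interval on which
the fitted curve attains its steepest relative decrease, i.e. the
interval beginning at the knee.  The acceptance test asserts the raw
means are monotone non-increasing within Monte-Carlo noise and that the
estimate lands at $0.20 \pm 0.05$.

## What the synthetic membranes do and do not emulate

The sweep's membranes are uniform random deuteration fields on an ideal
square lattice with a single reactive walker.  Real membranes have
correlated lipid composition, multiple concurrent radicals, chain
branching and termination chemistry, and non-square packing; none of
that is modeled, so passing tests certify the simulator and the stated
model, not quantitative membrane biochemistry.  Likewise the ecology
examples are qualitative demonstrations (coexistence, exchangeability,
shell formation) on small lattices, asserted as majorities over
replicates, not parameter-calibrated ecosystems.

## Problem sizes in the test suite

Unit tests use lattices between 2 and ~1600 sites; the oracle-equivalence
acceptance check runs ≥1000 events per example model on 12×12 lattices;
sampler-exactness tests use 10⁴ replicates on ≤4-site graphs against the
matrix-exponential law and 10⁴ holding times for the exponential-law
test; the deuteration sweep uses the full 101×101 lattice with 2000
replicates per point.  These sizes were picked so the whole suite
completes in minutes while every assertion retains comfortable
statistical power.

## Known limitations

* Mass-action kinetics between immediate neighbors only; no long-range
  interactions.
* No reaction–reaction dependency graphs (next-reaction/sorting-direct
  samplers) — with sample classes the dependency structure is not
  determined by participating species alone, and the linear cumulative
  scan is adequate at the packaged channel counts.
* No adaptive τ selection; skipped-event counts are the user's
  diagnostic.
* No hexagonal-close-packed 3-D lattice and no diffusion-coefficient
  calibration of lattice hop rates.
* `SimState` mutation is single-threaded; replicates parallelize at the
  process level if needed.
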