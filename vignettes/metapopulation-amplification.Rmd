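---
title: "Modelling beneficial-mutant spread in metapopulation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling beneficial-mutant spread in metapopulation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamp)
```

## The model

`metamp` simulates competition between a sensitive wild type and an
antibiotic-resistant mutant for a finite number of spaces in each patch
of a small metapopulation.  A patch `i` has `n_i` spaces (1,600 in the
reference configuration), each empty or occupied by one agent.  A
generation consists of three phases.

**Death.** An agent of type τ is removed with probability
`min(1, Z_τ · A)`, where `A` is the antibiotic concentration and `Z_τ`
the type's first-order kill coefficient.  The ratio `ρ = R/Z` — the
*normalized resistance* — is the antibiotic concentration at which the
type is eliminated outright.

**Birth.** An agent of type τ reproduces into an empty space of its own
patch with probability `R_τ · empty/K` — reproduction slows as the
patch fills, as in logistic (Lotka–Volterra) growth.  *Death and birth
propensities are both evaluated on the generation-start state*
(synchronous update).  This is a deliberate choice: it is the unique
arrangement under which the deterministic balance `N·R·(1 − N/K) =
N·Z·A` holds, so a single-type patch equilibrates at the effective
carrying capacity

$$N^\* = \left(1 - \frac{Z A}{R}\right) K ,$$

which the stochastic model reproduces to within Monte-Carlo error
(e.g. 1200 of 1600 spaces at `Z·A/R = 0.25`).  Computing the birth
probability from the post-death state instead would shift the
equilibrium to `K(1−2q)/(1−q)²` (with `q = Z·A/R`), breaking that
correspondence.  When proposed offspring exceed the free spaces left
after death, exactly `empty` offspring are kept by sampling without
replacement from the proposal pool — a hypergeometric allocation that
is unbiased between types.

**Migration.** Each agent attempts migration with probability `m` and,
if it migrates, picks a neighbour with probability proportional to the
outgoing edge weight.  Moves are resolved one at a time in a uniformly
random global order; a move into a patch with no free space at that
moment is aborted (the agent stays).  Agents in a node without
outgoing edges (the leaves of a rooted star) never move.  Migration
conserves the total agent count exactly; rejection rather than
displacement was chosen because displacement would smuggle in a death
mechanism the phase rules do not contain.

Because agents are exchangeable within a type, the state is stored as
per-node counts and the phases draw binomial/hypergeometric/multinomial
variates; this is distributionally identical to per-agent iteration and
is what makes 100-replicate sweeps take seconds.

An optional **bottleneck** operator thins every patch binomially
(survival fraction `f`) every `bottleneck_every` steps, emulating the
serial-transfer dilution of a daily-passage experiment; smaller `f`
means stronger drift.

## Time scale

One step is one generation of the simulation, identified with one
doubling time `t` (default 30 minutes), so an experiment of `d` days
corresponds to `round(d·24·60/t)` steps — 240 steps for five days
(`steps_for_days()`).

## Parameters, defaults, and why

| parameter | default | meaning and rationale |
|---|---|---|
| `A` (antibiotic) | 0.25 | arbitrary concentration units; with `Z_mut = 1`, `R = 1` it puts the mutant at 75% of its drug-free capacity — subinhibitory for both types |
| `Z_mut`, `R` | 1, 1 | the mutant's kill coefficient and growth propensity; `R = 1` means one expected division per doubling time at low density |
| `Z_wild` | 1.4 | from `calibrate_wild_kill(advantage = 0.1)`: the mutant's *invasion fitness* — its per-step growth factor in a patch of wild type at its own carrying capacity — is `1 + (Z_w − Z_m)·A = 1.1` |
| `m` (migration) | preset | presets set `m` through the expected-migrants diagnostic (below) |
| founders | 1000, 1 mutant | 1:1000 founding ratio; the mutant starts in leaf `P3`, never the hub |
| `n_steps` | 240 | five experiment days |
| bottleneck | every 48 steps, `f = 0.05` (bottleneck presets only) | one thinning per experiment day; 5% survival is a scaled stand-in for serial-transfer dilution at laboratory census sizes the 1,600-space patches cannot represent literally |

Two calibration choices deserve comment because the quantitative
settings behind the reference experiments are not published as numbers
and had to be fixed once:

* **Selection strength.** The resistant mutant's advantage is defined
  at the wild type's equilibrium (invasion fitness), which is where the
  competition actually happens and how competitive fitness is measured
  experimentally, rather than in an empty patch.  The default of 10%
  per step makes a within-patch sweep from a single copy take ~70
  generations to majority, so that patch-to-patch spread through four
  patches plays out across — and remains visible within — the 240-step
  observation window.  A 20–30%-per-step advantage compresses the whole
  metapopulation transition into the first half of the window and every
  between-arm comparison at late steps degenerates to
  establishment-probability noise.
* **Migration levels.**  The per-edge expected number of mutant
  migrants at the mutant's effective carrying capacity, `m·K·(1 −
  A/ρ)`, is the natural dimensionless migration scale: spread is
  colonization-limited below ~1 and migration-saturated far above it.
  The presets map low / intermediate / high to ≈ 0.1 / 1 / 10
  (`migration_for_em()` inverts the formula).

Dispersal asymmetry in the star presets is encoded as the weight ratio
of the two edge directions (default 2:1); only the direction of the
asymmetry, not its magnitude, is anchored in the reference experiments,
so the ratio is exposed as `asymmetry_ratio`.  The hub is node `P2`
and the introduction leaf is `P3` throughout, for consistency with the
four-patch naming convention.

## The exact oracle

On tiny instances the model's full Markov chain is tractable:
`enumerate_states()` lists every feasible count vector (a node of
capacity `K` has `(K+1)(K+2)/2` local states), `phase_kernel()` builds
the exact transition matrix of each phase under the same distributional
rules as the simulator — including the hypergeometric birth trim and
migration as the exact mixture over per-agent decisions, multinomial
destinations, and uniformly random move orders with full-node rejection
(resolved by memoized enumeration) — and `fixation_table()` solves the
standard first-step system for the probabilities that a chain started
in any mixed state first hits mutant fixation (no wild type left),
wild fixation, or extinction, plus the expected absorption time.

Because death and birth are synchronous within a generation, their
*stand-alone* kernels compose into the one-step kernel only in the
drug-free case (where death is the identity); the one-step kernel is
therefore built from an exact *joint* death+birth ("growth") kernel
composed with migration.  The test suite verifies row-stochasticity,
the drug-free composition identity, neutral symmetry, agreement of the
linear solve with brute-force forward iteration, and — the central
validation — agreement of simulator fixation frequencies with the
exact probabilities within three binomial standard errors at 10⁴ runs
on one-patch (K ≤ 3) and two-patch (K = 2) instances.

## Observables

* `metapop_fraction()` / `traj_fractions()` — mutants over total
  agents; undefined for an empty metapopulation.  In ensemble
  averages, a replicate is excluded from the mean from its extinction
  step onward and counted separately: imputing 0 would conflate
  extinction with wild-type fixation.
* `time_to_majority()` — first step at or above 50% (the threshold is
  a parameter).
* `per_node_spread_order()` — nodes ranked by first crossing of a
  within-node mutant fraction threshold (default 50%; ties broken by
  node id, never-reached nodes flagged last).
* `expected_migrants()` — the migration diagnostic above.
* `amplification_curve()` — per-step star-minus-mixed difference of
  mean fractions with pooled standard error; positive values at
  intermediate steps that fade late would be the signature of
  transient amplification.

## Logistic spread summaries

`fit_logistic()` fits the three-parameter logistic
`plateau / (1 + ((plateau − N0)/N0)·exp(−r·t))` to a trajectory of
mutant proportions by Levenberg–Marquardt nonlinear least squares on
the proportion scale, with `N0` fixed to the known founding proportion
(0.001 by default), leaving the spread rate (`r_max` analogue) and the
final-frequency plateau (carrying-capacity analogue) free.  The
initialization is deterministic — rate from the log-slope of the
early, below-half-plateau points; plateau from the largest observed
proportion, bounded into `(N0, 1]` — so fits are reproducible, and the
returned fit never has a larger residual sum of squares than its
initialization (a bounded quasi-Newton fallback covers the rare LM
failures; unconverged fits are flagged and carry no estimates).
Parameter recovery is exact to numerical precision on noiseless data;
under Gaussian measurement noise (sd 0.02) on a design that covers the
full sweep, the mean bias of the recovered rate is well under 5%.
Identifiability caveat: on designs that truncate the curve far below
its plateau the rate and plateau are jointly unidentifiable under
noise and the rate estimate is biased upward — fits should span the
saturation phase.

## What the generator emulates, and what it does not

The scenario presets emulate the *structure* of a four-patch
serial-transfer evolution experiment: topology (balanced, inward- and
outward-weighted stars; well-mixed control), migration level, founding
conditions, observation window, and optional daily bottlenecks.  They
do not emulate: de novo mutation (runs start with the one resistant
lineage and none arise later), within-patch spatial structure, explicit
resource dynamics, day-granular transfer mechanics (migration here is
continuous across generations rather than a once-daily pooling event),
or laboratory census sizes (1,600 spaces stand in for ~10⁹ CFU, so
drift is far stronger per capita than in the wet system).  Passing
tests therefore validate the model's internal consistency and its
stated regimes, not quantitative agreement with any particular wet-lab
measurement.

## A structural finding about balanced stars

With the migration rule as specified — each agent migrates with the
same probability `m` in every arm and splits its destination across
outgoing edges — the balanced star cannot exceed the well-mixed
control in *mean* metapopulation mutant fraction.  Both arms have
identical within-patch dynamics and identical total outflow from the
introduction patch; the well-mixed graph spreads that outflow over
three first-hop targets while the star concentrates it on one.  The
expected number of colonized patches under cumulative seeding pressure
`x` is `3(1 − e^{−x/3})` (well-mixed) versus `1 − e^{−x}` (star) —
weakly larger for every `x` by concavity — and at every later stage
the complete graph's route set strictly contains what the star can
use.  Simulations at 400 replicates per arm across migration levels
confirm it: the star-minus-mixed gap is never positive beyond noise
and is strongly negative mid-transition.  Topology-driven
*amplification* in this framework therefore requires something beyond
fixed, symmetric per-agent migration: inflow-weighted dispersal into
the hub, arm-specific migration calibration (e.g. matching the number
of migrants each patch *receives*), or stronger drift coupling — which
is why the package exposes dispersal asymmetry and bottleneck presets.
Under inward-weighted migration the star's disadvantage narrows, and
the hub-first spread order remains a robust star signature either way.

## Numerical choices and degenerate inputs

* RNG: one seed per replicate (`base_seed + replicate − 1`), recorded
  in trajectories and metadata; runs are bit-for-bit reproducible.
* Migration draws happen in a fixed node/type order, then a single
  global shuffle orders the moves; this avoids node-order artifacts.
* `enumerate_states()` refuses state spaces above 2×10⁵ states and
  dense kernels above 3,000 states, with the computed size in the
  error.
* Empty metapopulations: fractions are errors (`metapop_fraction`) or
  `NA` (trajectory level); the empty state is absorbing.
* Zero-weight edges are dropped by the builders; a node whose
  out-weights are all zero simply never exports.
* Spread-order ties break lexicographically by node id.
* Logistic fits on constant data return a rate of ~0 with the plateau
  pinned at its lower bound.

## Problem sizes in the test suite

The suite validates the equilibrium at the reference patch size
(K = 1600, 50 replicates), oracle agreement at 10⁴ runs per tiny
instance, neutral exchangeability at 2×10³ runs, and the topology
comparisons at 50 replicates per arm over 240 steps — sizes chosen so
the entire suite completes in well under a minute per module while
keeping Monte-Carlo standard errors small relative to the tested
effects.
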