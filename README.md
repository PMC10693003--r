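# metamp

Agent-based simulation of a beneficial, antibiotic-resistant mutant
spreading through small metapopulations whose subpopulations are
connected as **star** or **well-mixed** networks.

## The scientific problem

Evolutionary graph theory predicts that some network topologies can act
as *amplifiers of selection* — raising the chance, or the speed, with
which a beneficial mutant takes over a structured population — while
classic migration–selection models predict little effect of topology.
The sharpest disagreement is the star: leaf subpopulations that exchange
migrants only through a central hub.  `metamp` is a simulator for this
question at the scale of a laboratory evolution experiment: four patches
of 1,600 spaces each, founded with 1,000 cells of which a single one is
a resistant mutant (1:1000), tracked for 240 generations (five days at a
30-minute doubling time), with migration, dispersal asymmetry, and
serial-transfer bottlenecks under experimental control.

## The model

Each patch `i` has `n_i` spaces, each empty or holding one wild-type or
one mutant agent.  Every generation has three phases:

* **Death** — an agent of type τ dies with probability `min(1, Z_τ·A)`,
  where `A` is the antibiotic concentration and `Z_τ` the type's
  first-order kill coefficient.
* **Birth** — an agent reproduces into an empty space of its own patch
  with probability `R_τ · empty/K` (logistic crowding).  Death and
  birth propensities are both evaluated on the generation-start state,
  so a single-type patch equilibrates at the **effective carrying
  capacity** `(1 − Z·A/R)·K`; proposals exceeding the free space are
  trimmed by sampling without replacement (unbiased between types).
* **Migration** — each agent moves with probability `m` to a neighbour
  drawn with probability proportional to the outgoing edge weight;
  moves resolve in a uniformly random global order and a move into a
  full patch is aborted.

The key diagnostic for the migration regime is the **expected number of
mutant migrants per edge per step** at the mutant's effective carrying
capacity, `m·K·(1 − A/ρ)` with ρ = R/Z the normalized resistance;
scenario presets place "low / intermediate / high" migration at ≈ 0.1,
1, and 10.

Two components make the package more than a simulator:

* an **exact Markov-chain oracle** (`enumerate_states()`,
  `phase_kernel()`, `fixation_table()`) that enumerates the full state
  space of tiny instances, builds the exact one-generation kernel under
  the same distributional rules as the simulator, and solves the linear
  system for mutant-fixation / wild-fixation / extinction probabilities
  — the simulator is validated against it to within Monte-Carlo error;
* a **three-parameter logistic fit** (`fit_logistic()`, NLS with the
  initial proportion fixed) that summarizes each spread trajectory by a
  rate (`r_max`) and a final-frequency plateau.

## Worked example

Twenty replicates of a balanced star at the intermediate migration
preset (≈ 1 expected migrant per edge per step, `m ≈ 8.3e-4`):

```r
library(metamp)
g <- build_star(3, 1600)          # hub P2, leaves P1/P3/P4
p <- sim_params(migration_prob = migration_for_em(1), n_steps = 240, seed = 42)
ens <- run_ensemble(g, p, n_reps = 20)
summ <- ensemble_average(ens)
summ
#> <ensemble_summary> 20 replicates, steps 0..240, 0 extinct
#>   mutant fixed in 13 replicates; median time to majority 106
#>   step mean_fraction           se n_alive
#> 1    0   0.001000000 0.000000e+00      20
#> 2    1   0.001200746 6.062026e-05      20
#> ...
per_node_spread_order(ens[[1]])
#>    node_id cross_step reached
#> P3      P3         51    TRUE
#> P2      P2         90    TRUE
#> P1      P1        135    TRUE
#> P4      P4        161    TRUE
fit_spread(summ, pooled = TRUE)
#>   replicate     r_max   plateau      sse converged
#> 1        NA 0.0588034 0.7914519 1.255031      TRUE
```

Reading the numbers: the mutant fixed in 13 of 20 replicates (the
single founding copy is often lost to drift), needing a median of 106
generations to reach 50% of the metapopulation.  In the shown
replicate the mutant takes over its introduction leaf P3 first (step
51), then the hub P2 (step 90), then the remaining leaves — the
hub-first signature of spread through a star.  The pooled logistic fit
summarizes the mean curve: spread rate ≈ 0.059 per generation toward a
plateau of ≈ 0.79 (the plateau is below 1 because replicates that lost
the mutant stay at 0).

A command-line front-end with `simulate`, `sweep`, `fit`,
`oracle-check`, and `presets` subcommands is installed at
`inst/cli/metamp.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/metamp.R", package="metamp"))')" presets
```

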