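# patrolnet

Agent-based simulation of how first-hand knowledge of conservation
law-enforcement patrols spreads through the social network of a hunting
community, and of how community structure shapes that spread.

Ranger patrols deter illegal hunting only insofar as would-be hunters know
about them. Knowledge is gained first-hand by encountering a patrol and then
passed along social ties, so the structure of a community's contact network —
in particular how evenly social contacts are distributed — governs how far and
how fast deterrence information travels. `patrolnet` is for conservation
scientists and modellers who want to explore that process *in silico*: it
simulates threshold contagion of patrol knowledge on small social networks and
quantifies the joint influence of patrol effort, individual propensity to
listen, and network skew.

## The model

* **Communities.** Simple connected graphs of `n = 40` individuals whose
  degree distributions are lightly, moderately or highly skewed towards the
  star-graph extreme (one hub connected to everyone, no other ties). Degrees
  are drawn from a discretised lognormal with mean degree 4 and preset sigma
  (0.2 / 0.6 / 1.2), then wired exactly by degree-sequence sampling. Skew is
  measured as the bias-corrected sample skewness of the degree sequence.
* **Seeding.** Patrol effort `E ∈ [0, 1]` seeds `round(E·n)` individuals with
  first-hand knowledge — by default the *least-connected* ones, since hunting
  is often concentrated in marginal, poorly connected community members (a
  best-connected variant is available).
* **Spread.** Over 50 discrete time-steps, an uninformed individual with at
  least `T` informed direct contacts (the listening threshold; `T > 1` gives
  complex contagion) becomes informed with per-step probability `L` (the
  listening probability). Updates are synchronous and knowledge is absorbing.
* **Summary statistic.** The area under the cumulative informed-count curve,
  `AUC = Σₜ informed(t)`, bounded by `n_steps × n = 2000`.
* **Experiment.** A full factorial sweep — 3 structures × `T ∈ {1,2}` ×
  10 `L` values × 6 `E` values (120 combinations) × 100 replicates, a fresh
  network per replicate — followed by per-stratum OLS regressions
  `AUC ~ E + L + E:L` with sign/significance coding
  (`+++`/`---` for p ≤ 0.01, `+`/`-` for 0.01 < p ≤ 0.05, `0` otherwise).

The stochastic dynamics are validated against an exact state-space
enumeration oracle (`exact_expected_counts()`) on small graphs.

## Worked example

```r
library(patrolnet)

net <- generate_network(40, "high", seed = 7)
net
#> <social_network> 40 individuals, 85 ties (structure: high)
#>   generator seed: 7
#>   degree range: [1, 36], mean 4.25
degree_skewness(net)
#> [1] 4.104216

tr <- run_diffusion(net, diffusion_params(T = 2, L = 0.4, E = 0.25))
tr
#> <trajectory> 50 steps over 40 individuals: 10 -> 36 informed, AUC = 1484
head(tr$counts, 10)
#>  [1] 10 10 10 10 10 10 11 12 14 16
```

Ten individuals (25% of 40, the least connected) start informed; with a
listening threshold of 2 the information takes a few steps to ignite, then
spreads to 36 of 40 people — the four remaining have too few contacts to ever
meet the threshold. The AUC of 1484 (of a possible 2000) is this run's rate
of information flow.

The factorial experiment and sign matrix (here a 10-replicate demonstration;
the default is 100):

```r
res <- run_grid(grid_config(replicates = 10, base_seed = 1))
table1_report(res)
#> Direction of the influence of E and L on information flow (AUC)
#> (+++/--- p <= 0.01; +/- 0.01 < p <= 0.05; 0 otherwise)
#>
#> structure  T    E    L    E:L
#> light      T=1  +++  +++  ---
#> light      T=2  +++  0    +++
#> moderate   T=1  +++  +++  ---
#> moderate   T=2  +++  0    +++
#> high       T=1  +++  +++  ---
#> high       T=2  +++  0    0
```

At `T = 1`, patrol effort and listening probability both raise AUC strongly
and their interaction is negative: the response saturates at 2000, so gains
from raising both at once are tempered. At `T = 2` spread rarely ignites at
low effort under the default network presets, so effort dominates; see the
methods vignette (`vignettes/patrol-knowledge-diffusion.Rmd`) for why, and
for the sensitivity of this pattern to network density.

A command-line wrapper with `generate`, `simulate`, `grid` and `regress`
subcommands is installed at `inst/scripts/patrolnet`.

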