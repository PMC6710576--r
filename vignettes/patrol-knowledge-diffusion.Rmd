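---
title: "Modelling the diffusion of patrol knowledge through hunting communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the diffusion of patrol knowledge through hunting communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patrolnet)
```

## The question and the model

Law-enforcement patrols can only deter rule-breaking among people who know
they exist. First-hand knowledge is acquired by encountering a patrol;
second-hand knowledge travels along social ties. `patrolnet` isolates that
single link in the deterrence chain — the *receipt* of information, not
belief in it or behavioural response to it — and asks how its speed depends
on three things: patrol effort, individual willingness to listen, and the
shape of the community's contact network.

The model is a discrete-time threshold contagion on a fixed simple graph of
`n` individuals (default 40):

1. **Seeding.** A fraction `E` (patrol effort, in `[0, 1]`) of the community
   starts informed: `round(E * n)` individuals, rounded half away from zero.
   By default the *least-connected* individuals are seeded, reflecting
   settings where hunting is concentrated among marginal people at forest
   edges whose patrol encounters are frequent but whose social reach is
   small. Degree ties are broken uniformly at random. A best-connected
   variant is provided for comparison.
2. **Spread.** At each of `n_steps` (default 50) synchronous time-steps,
   every individual who is uninformed at the start of the step and has at
   least `T` informed direct contacts (counted at the start of the step)
   becomes informed with probability `L`, independently of the others.
   Knowledge is absorbing: there is no forgetting or disbelief.
3. **Summary.** The informed count at the end of each step is recorded; the
   area under that curve, `AUC = sum of the per-step counts`, measures the
   rate of information flow. It is bounded by `n_steps * n` (2000 at the
   defaults) and attains the bound exactly when everyone is seeded.

The threshold `T` distinguishes simple contagion (`T = 1`) from complex
contagion (`T > 1`), where information must arrive independently from several
contacts before it is taken seriously.

## Parameters

| parameter | meaning | range / default |
|---|---|---|
| `n` | community size (individuals) | 40 |
| `E` | patrol effort: proportion seeded | `[0, 1]`; grid 0.05–0.30 |
| `L` | listening probability per step | `[0, 1]`; grid 0.1–1.0 |
| `T` | listening threshold (informed contacts needed) | `{1, 2}` |
| `n_steps` | time-steps of unspecified duration | 50 |
| `structure` | degree-skew preset of the community | light / moderate / high |

The factorial experiment (`run_grid()`) crosses 3 structures, 2 thresholds,
10 listening probabilities and 6 effort levels — 120 `(T, L, E)` combinations
— with 100 replicates per cell and a *fresh network for every replicate*,
i.e. 12,000 generated networks per structure and 36,000 simulated
trajectories in all.

## The synthetic community generator

Real hunting-community networks are not reproduced here; the generator
emulates one structural axis believed to matter most — how evenly direct
social contacts are distributed — while holding mean connectivity fixed.
Per-node degrees are drawn i.i.d. from a lognormal with mean degree 4 and
log-scale standard deviation set by the preset (`light` 0.2, `moderate` 0.6,
`high` 1.2), rounded and truncated to `[1, n - 1]`. Low sigma gives a
near-symmetric degree histogram; high sigma gives a heavy right tail in
which a handful of hubs hold a large share of ties, approaching the
star-graph extreme. The presets are configuration values, not constants:
both the mean degree and sigma can be overridden, so an empirically fitted
degree model can be swapped in without touching the rest of the pipeline.

Wiring is exact-degree: the drawn sequence is realised by igraph's
degree-sequence samplers (Viger–Latapy when connectivity is enforced — the
default, since an isolated fragment could never receive information and the
interest is in within-community spread — otherwise degree-preserving edge
switching, with an edge-switching plus component-joining-swap fallback).
Realised degrees always equal the drawn sequence exactly, which the tests
assert by multiset comparison.

Three repairs keep the draw well-defined at the margins:

* **Parity.** An odd-sum sequence has its smallest degree incremented (the
  minimal perturbation); if that degree is already `n - 1`, the largest is
  decremented instead.
* **Realisability.** Heavy-tail draws are occasionally non-graphical (for
  example two saturated hubs of degree `n - 1` alongside degree-1 nodes) or
  have fewer than `n - 1` edges and so cannot be connected. The draw is
  conditioned on realisability by redrawing, up to a retry budget.
* **Near-unique realisations.** Sequences such as `[3, 1, 1, 1]` admit
  essentially one simple graph; the samplers return it.

What the generator does *not* emulate: assortativity, clustering and
community substructure of real contact networks; tie weights and directed
or asymmetric communication; network dynamics (ties forming or dissolving
over the patrol period). Tests passing under this generator therefore show
that the *mechanisms* behave as specified, not that any particular real
community would show the same response surface.

## Numerical and design choices

* **Listening semantics.** `L` is applied once per eligible individual per
  step, not once per informed neighbour: listening is modelled as a property
  of the listener, and the threshold `T` carries the requirement for
  repeated independent transmission. A per-neighbour variant
  (`listening_model = "per_edge"`, success probability `1 - (1 - L)^k` with
  `k` informed contacts) is provided for sensitivity analysis and is covered
  by the same enumeration oracle.
* **Synchronous updates.** All transitions in a step use the step-start
  state. This is the standard convention for discrete-time threshold models
  and makes trajectories reproducible under a single RNG stream.
* **AUC convention.** The seeded state is not recorded as a curve point; the
  AUC is the sum of the 50 end-of-step counts, making the theoretical
  maximum exactly `50 * 40 = 2000`.
* **Seed derivation.** Each run of the factorial grid is seeded by an affine
  map (modulo the Mersenne prime `2^31 - 1`) of its index in the canonical
  grid order, offset by the experiment's `base_seed`. Seeds are therefore
  distinct across the design, fixed by the parameter tuple's canonical
  position, and independent of execution order — `run_grid()` accepts an
  explicit `execution_order` and the tests assert the output is identical
  under permutation.
* **Regression model.** Within each (structure, `T`) stratum, AUC is
  regressed on `E + L + E:L` by OLS with predictors on their natural scale
  and replicates pooled as independent rows — the simplest model consistent
  with the reporting convention; sign codes are invariant to positive
  rescaling of AUC, which the tests assert. The `p = 0.05` boundary is coded
  as significant (`+`/`-`): the conventional reading when the coding rule's
  inequalities overlap at the boundary.
* **Degenerate inputs.** Zero-variance degree sequences have undefined
  skewness and return `NA_real_` rather than erroring; `E = 0` seeds nobody
  and `L = 0` freezes the dynamics (`AUC = 50 * seeds` exactly); rank-
  deficient regression strata (a single `L` or `E` value) are rejected with
  an explicit error.

## Validation strategy

The stochastic simulator is checked against an independent exact oracle:
`exact_expected_counts()` propagates the full probability distribution over
knowledge states (state space `2^n`, refused above `n = 12`) and returns
exact per-step expected informed counts. The test suite compares Monte-Carlo
means with the exact values on path, cycle, star and hub-dominated fixture
graphs of 7–10 nodes, across `T ∈ {1, 2}` and `L ∈ {0.25, 0.5, 1}`, over 10
steps, with 100,000 replicates per configuration, requiring agreement within
three standard errors at every step. Deterministic corners (flood fill at
`L = 1, T = 1` against breadth-first distances, frozen dynamics at `L = 0`,
hand-enumerated small cases) are asserted exactly.

Experiment-level checks run the full default design (36,000 simulations) and
assert the accounting, the saturation bound, the regression sign pattern,
stochastic monotonicity of mean AUC in `L`, `E` (non-decreasing) and `T`
(non-increasing) with 1,000 paired replicates per comparison, and bitwise
reproducibility. These sizes keep the whole suite at a few minutes on a
single core while leaving the stochastic assertions well-powered.

## Known limitations

* **Complex contagion needs density to ignite.** Under the default presets
  (mean degree 4), a `T = 2` process seeded in 2–12 least-connected
  individuals frequently never starts: no one has two informed contacts.
  AUC then equals `50 * seeds` regardless of `L`, so on the natural
  predictor scale the `L` main effect in the `T = 2` strata is weak and `L`
  acts mostly through its interaction with `E`. A sensitivity probe at mean
  degree 8 shows the `L` main effect strengthening and the interaction
  shrinking, so conclusions about `T = 2` strata are sensitive to the
  community's density and minimum degree — exactly the features a fitted,
  rather than stylised, degree model would pin down.
* **Unreachable individuals.** A node with fewer than `T` contacts can never
  be informed unless seeded; with heavy-tailed presets a substantial
  minority has degree 1, capping `T = 2` coverage below `n`.
* **Scope.** Belief, trust, behavioural response, patrol adaptation, prey
  dynamics and spatial structure are deliberately outside the model: it
  simulates receipt of information only.
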