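---
title: "Reputation-inference dynamics in spatial social dilemmas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reputation-inference dynamics in spatial social dilemmas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(inferrep)
library(dplyr)
```

## The model

`inferrep` simulates evolutionary social-dilemma games on structured
populations in which imitation partners ("strategy donors") are selected by
*probabilistic reputation inference* rather than uniformly at random.

Players occupy the nodes of an undirected interaction network with four
neighbours per player on average — a periodic square lattice with von
Neumann neighbourhoods, a random 4-regular graph, or a Watts–Strogatz small
world grown from a degree-4 ring. Each player holds a strategy $s_i \in
\{C, D\}$, a reputation $R_i \ge 0$, and a fixed personal *inferring
ability* $p_i \in [0, 1)$ drawn once at initialisation from the uniform
distribution.

Two games are supported. The **weak prisoner's dilemma** has payoffs
$T = b$, $R = 1$, $P = S = 0$ with temptation $1 \le b \le 2$ (at the
boundary $b = 1$ the dilemma degenerates; it is admitted so that sweep
grids can anchor there). The **snowdrift game** uses the standard lattice
convention $T = 1 + r$, $R = 1$, $S = 1 - r$, $P = 0$ with cost-to-benefit
ratio $0 < r < 1$, satisfying $T > R > S > P$. The snowdrift entries are a
convention choice: only the payoff ranking and the meaning of $r$ are fixed
by the model class, so the parameterisation is isolated in
`payoff_matrix()` where an alternative convention could be substituted.

**Dynamics.** Time advances in full Monte Carlo steps (MCS). One MCS
consists of $N$ elementary events ($N$ = population size). Each event:

1. picks a focal player $x$ uniformly at random (random sequential update
   with replacement — the standard reading of "each player updates once on
   average per MCS");
2. selects a donor $y$: with probability $p_x$, a neighbour of maximal
   reputation (ties broken uniformly at random); otherwise a uniformly
   random neighbour;
3. computes both players' payoffs *fresh* against their current
   neighbourhoods (payoffs carry no memory across events);
4. lets $x$ adopt $s_y$ with the Fermi probability
   $W = 1/(1 + \exp[(P_x - P_y)/K])$, where $K > 0$ is the noise
   amplitude.

At the end of every MCS each player's reputation is updated once,
synchronously, from its current strategy with increment $\Delta R = 1$ for
cooperation and $0$ otherwise:

* **accumulative** rule: $R \leftarrow R + \Delta R$, starting from
  $R = 1$, so reputation equals one plus the lifetime count of cooperative
  steps and never decreases;
* **weighted** rule: $R \leftarrow (1 - w)R + w\,\Delta R$ with evaluation
  factor $w \in [0, 1]$ interpolating between frozen historical memory
  ($w \to 0$) and the instantaneous cooperation indicator ($w = 1$).

Setting every $p_i = 0$ removes the reputation channel entirely and
recovers the traditional spatial game (`traditional_baseline = TRUE`),
which serves as the comparison baseline throughout.

## Design choices in the ambiguous corners

Several micro-level details of this model class are conventionally left
implicit; the package fixes them as follows.

* **Reputation update timing.** Strategy updates are asynchronous but
  reputation is defined per "time step". We update all reputations once per
  MCS, synchronously, from end-of-step strategies — the only timing under
  which every player's reputation advances at the same rate. The
  alternative reading — incrementing only the focal player's reputation at
  each elementary event, from its post-event strategy — is available as
  `reputation_rule(timing = "per_event_focal")` through
  `monte_carlo_step()`, and the event-level dynamics are exposed
  (`run_elementary_steps()`) so any other bookkeeping can be driven from
  outside the engine.
* **Weighted-rule form.** The exponential-smoothing interpolation
  $(1-w)R + w\,\Delta R$ is the standard form that satisfies both stated
  limits (pure memory at $w \to 0$, pure present behaviour at $w \to 1$).
  It lives behind the `reputation_rule()` abstraction.
* **Tie-breaking.** Equal-maximal-reputation neighbours are chosen
  uniformly (reservoir sampling in the engine); any deterministic rule
  would bias donor selection in the early, tie-rich phase.
* **Boundary conditions.** The lattice is periodic with von Neumann
  (degree-4) neighbourhoods, matching the mean degree of the other
  topologies and making neighbour structure translation invariant.
* **Watts–Strogatz dialect.** The small world starts from a degree-4 ring;
  each edge is independently rewired with the given probability to a
  uniform non-self, non-duplicate target, keeping the edge count (hence
  mean degree 4) exact. The random regular graph comes from igraph's
  k-regular sampler with simplicity enforced.
* **Numerical safety.** Fermi exponents are clipped at $\pm 700$ before
  exponentiation; on degree-bounded graphs the engine precomputes the full
  table of adoption probabilities over (strategy, degree, cooperating
  neighbours) pairs, so no transcendental function is evaluated in the
  event loop and results are reproducible bit-for-bit under a seed.
* **Early absorption.** All-$C$ and all-$D$ are absorbing; runs stop there
  and extend the absorbing cooperator fraction through the remaining
  trajectory (donor counters become missing). This changes no expectation
  value and bounds runtime.

## Observables

`run_simulation()` records the cooperator fraction $\rho_c$ after every
MCS together with three donor-selection counters per MCS: $N_h$ (events
whose donor came from the highest-reputation branch), $N_{hc}$ (those
donors that were cooperators) and $N_{rc}$ (randomly chosen donors that
were cooperators). `donor_statistics()` derives two ratios from them —
$f_h = N_{hc}/N_h$, the cooperator share among reputation-selected donors,
and $f_{share} = N_{hc}/(N_{hc} + N_{rc})$, the reputation-selected share
among all cooperator donors. The exact functional forms of such statistics
are not pinned down by the model class; these are the two ratios
constructible from the three counters, both are exposed, and tests rely
only on their qualitative trends. Zero-denominator ratios are reported as
missing, never as zero.

Cooperators are classified `"high"` if their reputation strictly exceeds
that of *every* neighbour (any tie forces `"low"`), defectors are left
unclassified; `cluster_statistics()` cross-tabulates these labels against
cluster membership and boundary status (a cooperator with at least one
defector neighbour) under the game adjacency.

```{r quick-run}
cfg <- sim_config("weak_pd", parameter = 1.03, side_or_n = 30,
                  relaxation_mcs = 500, measurement_mcs = 200, seed = 7)
res <- run_simulation(cfg)
glance(res)
```

```{r trajectory-plot}
autoplot(res)
```

## Experiment drivers

* `sweep_parameter()` runs independently seeded replicates over a grid of
  the game parameter (or of $w$) and returns per-point means with standard
  errors. Replicates are capped at 40 per point, the customary averaging
  depth for this model class.
* `estimate_extinction_threshold()` scans the temptation at fixed
  resolution and classifies a grid point *extinct* iff every replicate's
  stationary $\rho_c$ falls below $\varepsilon = 10^{-3}$; with early
  absorption this is literal fixation for essentially every run, and
  $\varepsilon$ only guards non-absorbed stragglers. The threshold $b_c$
  is the midpoint between the last surviving and first extinct grid point;
  scans that never cross report a censored bound, and re-entrant survival
  above the first extinction is flagged rather than silently averaged. The
  simulator is injectable (`simulate_fn`), which is how the scanner itself
  is verified against noise-free surrogate dynamics with a planted
  threshold.
* `map_phase_diagram()` classifies each $(b, K)$ point as `pure_C`
  (all replicates fixate to cooperation), `pure_D` (all fixate to
  defection) or `mixed`, and `phase_boundaries()` reads off the two
  transition lines as midpoints between adjacent grid values. No
  interpolation or finite-size scaling is attempted.

The `inferrep` executable (installed under `exec/`) wraps these drivers as
`simulate`, `sweep`, `threshold`, `phase` and `snapshot` subcommands; every
invocation writes its results as CSV plus a JSON manifest with the full
configuration, so runs are reproducible from the manifest alone.

## Problem sizes and what the checks do and do not show

Simulations in this document and in the test suite are chosen small enough
to iterate comfortably: the threshold scans use the $100 \times 100$
lattice with $2\times10^4$ relaxation plus $5\times10^3$ measurement MCS
and 10 replicates per grid point; comparative sweeps (mechanism dominance,
snowdrift, $w$-sweeps) use $50 \times 50$ with $5\times10^3 + 10^3$ MCS,
and the coarse phase maps $40 \times 40$ with $4\times10^3 + 10^3$ MCS.
These sizes resolve the qualitative structure of the model; they are
generator defaults of the experiment scripts, not constants of the model,
and all are configurable.

Two systematic effects of the protocol scale deserve mention.

* **Fixation-based extinction underestimates asymptotic thresholds.**
  Near criticality the coexistence density vanishes continuously, so on a
  finite lattice the absolute number of surviving cooperators becomes
  small and demographic fluctuations drive absorbing extinctions at
  temptations where an infinite system would still coexist. Threshold
  estimates from this protocol are therefore systematically a little below
  the values that large-lattice, coexistence-criterion studies report; the
  effect is strongest for slowly relaxing near-critical points.
* **Accumulative reputation is retrospective.** Because the accumulative
  rule never decreases, a long-standing cooperator that switches to
  defection retains its accumulated reputation for a long time and keeps
  being selected as a donor *while defecting*. At late times this
  "reputational inertia" partially undermines the cooperator-promoting
  channel: donor discrimination ($f_h$) is strongest early, when
  reputation differences reflect current behaviour, and weakens as
  reputational capital accumulates. The weighted rule removes this inertia
  at rate $w$, which is precisely why intermediate $w$ can outperform both
  extremes.

The synthetic dynamics emulate the model class faithfully but idealise
real systems: populations are fixed-size with no mutation or migration,
payoffs are noiseless, reputation is objective and globally consistent
rather than an aggregate of opinions, and inferring abilities are static.
Passing tests demonstrate internal correctness of the simulator and the
qualitative phenomenology of the model at the stated sizes — not
quantitative agreement with any empirical social system.
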