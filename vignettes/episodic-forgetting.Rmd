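---
title: "Episodic control with forgetting memories: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Episodic control with forgetting memories: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the model it simulates, the
parameters that matter, the design choices that were genuinely open, and what
the simulations do and do not show.

## The task and the agent

The agent forages in a 20×20 lattice gridworld. Each non-obstacle cell is a
state; the four actions Down, Up, Left, Right move the agent one cell, and an
action into a wall or off the grid leaves it in place. Every occupied state
pays a step penalty of −0.01 except a single reward state worth +10. An
episode starts at a uniformly random available state, ends when the agent
occupies the reward state, and is capped at 250 reward receipts: a fully
failed episode therefore scores exactly 250 × (−0.01) = −2.5, and an optimal
path of geodesic length *d* scores 10 − 0.01·*d*. Four layouts are provided:
an open field (400 states), a separated field (a vertical wall with one gap),
four rooms (a cross of walls with four doorways; 365 states), and a tunnel (a
one-row corridor). Only the four-rooms layout is pinned by a published state
count; the other walled layouts are reconstructions of the depicted mazes, and
their obstacle lists live in a single data file (`R/layouts.R`) so they can be
revised without touching code.

The agent is an *episodic controller*: it keeps no parametric value function.
Its memory bank is a capacity-limited dictionary of at most *N* entries, each
holding a state-encoding key, a 4-slot array of Monte-Carlo returns (one slot
per action), and a last-update timestamp. At each step the bank is queried
with the current state's encoding; the entry with the smallest Chebyshev
(L∞) distance is recalled and a unit-temperature softmax over its return
slots gives the policy. At the end of each episode the discounted returns
G_t = Σ_k γ^k r_{t+k} (γ = 0.98 throughout) are computed by backward
recursion and each (state, action, return) tuple is written to the bank:
update-in-place for stored states, append for novel states, and — once the
bank is at capacity — overwrite of a victim chosen by the forgetting rule.
Capacity is a fraction of the environment's available states, rounded down
(so 75% of 400 is 300 and 75% of 365 is 273); at fraction 1 every state fits
and nothing is ever forgotten.

Two forgetting rules are implemented: `oldest` overwrites the entry with the
minimal timestamp, `random` draws a victim uniformly. Timestamps are by
default refreshed on *writes* only; a `forget_on = "access"` switch makes
recall refresh them too, because the two readings ("least recently updated"
vs "least recently accessed") describe different caches and only the first
is operationally pinned by the storage protocol. The default is `update`.

## State encodings

Four key spaces are provided, all with one row per available state and, by
construction, pairwise-distinct rows:

* **onehot** — a unit indicator; any two distinct states sit at Chebyshev
  distance exactly 1, so keys carry no relational information.
* **random** — i.i.d. Uniform[0, 1) entries; dimension is set to the number
  of available states so all encodings share key dimensionality (nothing in
  the model pins this; it makes the four conditions comparable).
* **place cell** — one isotropic Gaussian unit per state, centred on that
  state's grid-normalised coordinates (grid units / 20), with width σ = 0.05
  — one cell. Activity depends only on Euclidean distance, so place-cell
  keys *ignore walls*.
* **successor representation (SR)** — row *s* of M = (I − γT)⁻¹, the expected
  discounted future occupancy under a uniform random walk, computed by a
  linear solve rather than an explicit inverse. T is built from the lattice
  dynamics, with self-loops where actions are blocked, so SR keys *feel
  walls*. Every row of M sums to 1/(1−γ) = 50 at γ = 0.98, which the tests
  use as a closed-form check.

The exponent of the place-cell Gaussian is implemented as the standard
isotropic form −[(x−x_i)² + (y−y_i)²]/(2σ²); peak activity is
1/(2πσ²) ≈ 63.66. Place-cell centres exist only on available states (no
units inside walls).

## Why storage order matters

The memory bank behaves exactly like an insertion-ordered dictionary: an
update keeps an entry's position, and forgetting removes the victim and
appends the replacement at the end. Non-exact recall ties are broken by the
*first* minimal entry in that storage order (a `tie_break = "random"` option
exists). This detail is invisible for structured encodings, where ties are
measure-zero, but decisive for onehot keys: every non-exact candidate ties at
distance 1, so the recalled entry is always the oldest-inserted one. With
fixed-slot storage instead, a single long-lived slot would supply the policy
for *every* uncovered state, giving the onehot agent an artificial coherent
drift; with dictionary order the fallback policy is a stale, frequently
replaced entry, and severely capacity-limited onehot agents behave close to a
random walk — the behaviour the model family is meant to exhibit.

Other conventions fixed here, with their reasons:

* Unvisited action slots enter the softmax as 0. The softmax needs four
  finite numbers; with returns in [−2.5, 10] a single large stored return
  then dominates, which is what produces confident policies near the reward.
* Exact match means Chebyshev distance exactly 0 — safe because queries and
  keys are rows of one precomputed table, so matches are bitwise.
* The softmax subtracts the maximum before exponentiating (exact, by shift
  invariance).
* Episode starts exclude the reward state (a start there would be a
  zero-length episode).
* The optimal average score R* = 10 − 0.01·λ uses λ = mean geodesic distance
  to the reward over all available states *except* the reward itself,
  matching the start-state distribution; including it changes λ by < 0.3%
  on these grids.
* Retrieval reduces to lookups in the precomputed pairwise Chebyshev matrix
  of the encoding (`encoding_distances()`), which is exact and makes long
  runs cheap; `recall()` also accepts raw vectors and the tests check both
  routes against a scalar-loop scan.

## Performance measures

Raw episode scores are normalised to 100 × (mean + 2.5)/(R* + 2.5), so an
all-fail run maps to 0% and an optimal agent to 100%. Chance level is the
same normalisation applied to a memory-free random-walk agent. Policy maps
query the bank for every available state through the ordinary recall path;
from each per-state policy we compute the preferred direction z_s (the
policy-weighted sum of the four cardinal displacement vectors) and the
Shannon entropy in nats (range 0 to ln 4 ≈ 1.386; the log base is a
convention, entropy in the model is only ever compared, never interpreted in
bits). Direction and entropy fields are averaged over late-run memory
snapshots, after the bank has reached its capacity limit. Retrieval match
statistics (exact-match percentage per recall event, and mean distance of
non-exact recalls) are aggregated separately for successful and failed
episodes; "per event" rather than "per episode" because memory is queried at
every timestep. Forgetting incidence divides each run's per-state overwrite
counts by its total forgetting events (so each run's frequencies sum to 1),
averages across runs, and the oldest-minus-random difference field shows
which states the oldest rule preserves (negative) or discards (positive)
relative to chance. Welch's unequal-variances t-test with Bonferroni
correction over planned comparisons is used for all condition contrasts; it
is implemented from the formula and cross-checked against `stats::t.test()`
in the tests.

## Problem sizes used by the tests

Full study conditions (the `simulation_config()` defaults) are 5000 episodes
per run and six seeds per condition. The test-suite reproductions use
reduced scales chosen so the stochastic contrasts are still decisive: the
capacity-restriction battery runs the open field at 1000 episodes × 5
matched seeds for capacity fractions 1, 0.75 and 0.25; the forgetting-rule
incidence comparison runs four rooms at 1000 episodes × 6 seeds per rule at
75% capacity; the policy-field contrasts average the last 50–100 per-episode
snapshots of 600–1000-episode runs. At these scales the capacity battery
reproduces the qualitative pattern: no encoding difference with unbounded
memory, a significant structured-over-unstructured advantage at 75%
capacity, and a collapse of onehot (but not SR) toward the random-walk
baseline at 25% — in our runs the onehot agent settles roughly 10–15
normalised points above baseline at that scale rather than strictly within
10, which is worth knowing when comparing against full-scale results.

## What the simulations do and do not show

Everything here is generated by the package itself: environments are
procedural, encodings are computed from the environment graph, and episodes
are pseudo-random trajectories. The model world is stationary (one fixed
reward, deterministic dynamics, no sensory noise, no contextual cues), so
passing tests show that the *mechanism* — structured keys plus moderate
forgetting yielding generalising, confident policies — behaves as described
in this idealised setting. They say nothing about non-stationary rewards,
continuous state spaces, perceptually aliased observations, or
salience-weighted forgetting, all of which are outside the model. Monte-Carlo
returns require episodic (terminating) structure and backward replay;
bootstrapped (TD) value estimates are deliberately not implemented.

```{r example, eval = FALSE}
library(epiforage)

grid <- experiment_grid(
  layouts = "open_field",
  encodings = c("onehot", "successor"),
  fractions = c(1, 0.75, 0.25),
  seeds = 1:5, n_episodes = 1000
)
res <- run_experiment(grid)
glance(res)
autoplot(res, chance_level = 21.9)
```
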