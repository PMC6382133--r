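---
title: "Methods: learning-agent swarms on a ring and their Fokker–Planck description"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: learning-agent swarms on a ring and their Fokker–Planck description}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`psmarch` simulates a group of `N` agents on a one-dimensional periodic
arena of `W` discrete blocks. Every agent carries a heading
`σ ∈ {−1, +1}` and moves one block per time-step; agents pass through
each other freely. An agent perceives the *net flow* of conspecifics
within ring distance `r`: the count of neighbours sharing its heading
minus the count opposing it, clipped to the percept space
`s ∈ {−2, −1, 0, +1, +2}`. The ratio `B = W/(2r)` is the number of
non-overlapping neighbourhoods the arena supports, and the effective
density `N/B` is the control parameter of the collective dynamics.

Each agent is a minimal projective-simulation (PS) agent: a two-layer
clip network whose five percept clips connect directly to two action
clips — turn around (`a = −1`) or continue (`a = +1`). The edge weights
("h-values", all `≥ 1`) form a 5 × 2 matrix; deliberation is a one-hop
random walk, so the response probabilities are the normalised row,
`P(a|s) = h(s,a)/Σ_{a'} h(s,a')`. After acting, the agent is rewarded
(`R = 1`) iff it moves with the strict majority of its neighbours, and in
learning mode it updates every edge by reinforcement with forgetting:
`h' − 1 = (1 − γ)(h − 1)`, plus `R` on the edge just used. Damping pulls
h-values towards 1 (not 0), which keeps the normalisation well-behaved
and lets the agent re-randomise a response that stops being rewarded.

The fixed-disposition mode bypasses learning and equips all agents with
`h(+2,+1) = h(−2,−1) = 1 + d`, `h(+1,+1) = h(−1,−1) = 1 + d/2`, all other
entries 1. This reduces the agent to a self-propelled particle whose
single parameter `d` (decisiveness) measures how reliably it follows the
local net flow. An optional inertia `ι` raises `h(0,+1)` to `1 + ι`,
making continuation the preferred response to a zero net flow; its
default is 0 and turning it on has no qualitative effect on anything
reported here.

## Parameters

| parameter | meaning | default / standard values |
|---|---|---|
| `W` | world size, blocks | 80 |
| `r` | sensory range, blocks | 5 (so `B = 8`) |
| `N` | population size | 10 / 40 / 70 |
| `d` | decisiveness (fixed mode) | 1 / 5 / 30 |
| `γ` | forgetting per own interaction | 0 or 0.002 |
| `ι` | inertia on `h(0,+1)` | 0 |
| `steps` | sweeps per run | experiment-specific |

`preset_config()` exposes the standard combinations (`"fig2a"`–`"fig2c"`
fixed mode at `d = 30`, `"fig4a"`–`"fig4c"` learning at `γ = 0.002`,
`"fig7"` learning at `γ = 0`).

## The asynchronous sweep

One time-step (a *sweep*) cycles through the agents in a fixed index
order: agent `i` perceives, deliberates (consuming exactly one uniform
variate), flips its heading if it chose to turn, and is rewarded against
its neighbours' *current* headings — those earlier in the order have
already acted this sweep, later ones have not. Sequential updating is
deliberate: no agent deliberates while a neighbour is mid-decision, which
is both more realistic for animals than synchronous updating and cleaner
for reinforcement learning (each agent can attribute the outcome to its
own choice). After the `N`-th turn all agents advance one block along
their headings; `z` is recorded after each completed sweep, with index 0
the random initial state.

Decisions that the verbal model leaves open are resolved as follows, each
switchable in the configuration:

* **Ties and isolation.** "Majority" is read strictly: an exact tie or an
  empty neighbourhood gives `R = 0` (rewarding an isolated agent would
  reinforce arbitrary actions). `reward_ties = TRUE` selects the lenient
  alternative.
* **Movement timing.** Displacement belongs to the time-step, not the
  turn, so all agents move after the last turn of the sweep
  (`move = "per_sweep"`); `move = "per_turn"` moves each agent
  immediately after its own turn. The two differ only in within-sweep
  bookkeeping; all defaults reported here use per-sweep movement.
* **Initialisation.** Positions i.i.d. uniform over blocks, headings
  i.i.d. uniform `±1`.
* **Randomness.** A single global RNG stream is consumed in turn order,
  so a configuration plus a seed determines every output bit. The
  compiled core and the pure-R reference sweep (`sweep_swarm()`) consume
  the stream identically and are cross-checked draw-for-draw in the
  tests.

# Fokker–Planck analysis

The group alignment `z = (1/N) Σ σ_i` lives on the grid `(2m − N)/N`.
Its probability density evolves, on coarse time-scales, under a
Fokker–Planck equation with drift `F(z)` and diffusion `D(z)`. The
package derives these coefficient functions from the individual-level
rules in three independent ways, all per unit sweep:

1. **Monte-Carlo transition kernel** (`estimate_transition_kernel()`):
   for each grid `z`, swarms are drawn with exactly `N(1+z)/2` positive
   headings (assignment random) and uniform positions, one sweep of the
   fixed policy is applied, and `z′` is histogrammed. The Kramers–Moyal
   coefficients follow as `F(z) = E[z′ − z|z]` and
   `D(z) = ½ E[(z′ − z − F)²|z]` (`km_from_kernel()`). The central
   second moment is the default; the non-central variant differs by
   `F²/2`, negligible near fixed points, and is available via
   `central = FALSE`.
2. **Mean field** (`meanfield_drift_diffusion()`): the focal agent sees
   `k ~ Binomial(N−1, 1/B)` neighbours whose headings are i.i.d. `+1`
   with probability `(1+z)/2`; summing the policy's turn probability over
   the exact (finite) percept distribution gives the per-heading flip
   probability `q(σ, z)`, whence
   `E[z′] = ((1+z)/2)(1−2q(+1,z)) − ((1−z)/2)(1−2q(−1,z))`,
   `F = E[z′] − z`, and `D = Var[z′]/2` with
   `Var[z′] = (1/N)(1 − Σ_σ w_σ (1−2q(σ,z))²)`. All sums are exact; for
   the neutral policy this collapses to the closed forms `F(z) = −z`,
   `D(z) = 1/(2N)`, which the tests verify to machine precision.
3. **Empirical** (`empirical_km()`): one-step increments of a long
   trajectory, binned by `z` after a burn-in, with under-visited bins
   flagged.

Fixed points are located by linear interpolation at sign changes of `F`
on the grid (`find_fixed_points()`); the slope at a root is interpolated
from centred finite differences, roots with negative slope are stable,
and Monte-Carlo roots whose `|F|` stays within twice its standard error
across a five-point neighbourhood are flagged low-confidence. Linear
interpolation is used deliberately — the model makes no claim that `F` is
a cubic, so no polynomial is fitted.

## Accuracy of the mean field

The mean field ignores two correlations that the kernel (which is
model-exact by construction, given its uniform-position conditioning)
retains: within-sweep sequential feedback (later agents react to flips
made earlier in the same sweep) and the discrete window geometry (it uses
neighbour probability `1/B = 2r/W` rather than the exact `(2r+1)/W`).
The net effect is a systematic drift offset of a few hundredths — at
`d ∈ {1, 5}`, `N ∈ {10, 40}` the maximum of `|F_mf − F_kernel|` over the
grid is 0.03–0.07, far outside Monte-Carlo error at useful sample sizes,
while the correlation between the two curves exceeds 0.98. (Substituting
the exact window probability makes the agreement slightly *worse*: the
two neglected effects partially cancel.) Tests therefore assert an
absolute band of 0.1 plus shape agreement, not a standard-error band.
The fixed-point structure is insensitive to this offset: at
`d = 30, B = 8` both routes give the same bifurcation, a unique stable
zero at the origin for `N = 10` and, for `N = 70`, an unstable origin
with a symmetric stable pair at `z ≈ ±0.94`. The same bifurcation occurs
when the decisiveness is raised at fixed density.

## What long simulations add — and where they disagree

The kernel conditions on uniform positions. The stationary state of the
actual spatial dynamics is *not* uniform: agents that happen to co-move
stay within range of each other indefinitely (equal speeds freeze
relative positions), so aligned clusters self-stabilise. Two
consequences, both visible in the tests:

* Empirical Kramers–Moyal drift from long `d = 5, N = 40` runs agrees
  with the kernel to ~2 standard errors in the well-visited centre but
  deviates systematically (up to ~0.04 in absolute terms) at large `|z|`.
* At `d = 30` the spatial simulation orders at *all* standard densities:
  even `N = 10` reaches a time-averaged `|z|` around 0.8, telegraphing
  between the two ordered directions with dwell times of only ~100–300
  sweeps, while `N = 40` and `N = 70` are nearly frozen (switch counts
  per 5000 sweeps of roughly 15 → 2.3 → 0.6 for `N = 10/40/70`). The
  uniform-position analysis, which predicts a disordered state at
  `N = 10`, misses the clustering that sustains this low-density order.
  The qualitative density dependence — direction changes becoming rapidly
  rarer and order more persistent as density grows — is robust; the
  *level* of `|z|` at low density is where the spatial and well-mixed
  descriptions part ways. At `d = 5` the simulation itself shows the
  three canonical regimes (time-averaged `|z|` ≈ 0.39/0.47/0.62 with
  ~225/26/3 direction changes per 2000 sweeps at `N = 10/40/70`).

# Trajectory summaries

`switching_statistics()` counts direction reversals with a two-threshold
hysteresis rule (default `θ = 0.3`): a switch is registered only when `z`
crosses from at or beyond one threshold to at or beyond the other, so
noise around zero is not counted. `regime_classify()` applies declared,
configurable conventions: *disordered* below time-averaged `|z|` of 0.3,
*ordered* at or above 0.6 with fewer than one switch per 1000 sweeps,
*intermediate* otherwise. These thresholds are operational definitions,
stated once and not tuned; under them the `d = 30` spatial runs classify
as intermediate/ordered/ordered across the three standard densities, for
the clustering reason above.

`learning_curves()` tracks ensemble response probabilities from memory
snapshots; the three tracked responses are maintaining direction under an
aligned net flow (`s = +2`), turning under an opposing net flow
(`s = −2`), and turning on zero net flow (`s = 0`, which should stay near
½ because neither action is systematically rewarded there — verified to
within ±0.1 throughout training).

## Learning dynamics

With forgetting (`γ = 0.002`, `N = 40`) the rewarded responses
equilibrate where reinforcement balances damping. The asymptotic
`P(+1|+2)` exceeds `P(−1|−2)`: as the group orders, opposing-flow
percepts become rare, so that edge is reinforced less often — an
encounter-frequency effect, not an asymmetry of the rules. The learning
timescale is quoted as the time for the ensemble-mean `P(+1|+2)` to
cover 90% of its rise from chance (½) to its value at sweep 5000; the
median over ten seeds is ~40 sweeps at a snapshot cadence of 5. (The
alternative convention — 90% of the *value* at sweep 5000 — is nearly
met at the start, since ½ is already half of the asymptote, and is
therefore not a meaningful timescale.)

Without forgetting (`γ = 0`) rewarded h-values grow without bound and
responses become deterministic. `P(+1|+2)` saturates above 0.999 within
10⁴ sweeps even at `N = 10`. `P(−1|−2)`, however, freezes near 0.91 at
that horizon: once the group fully aligns — which `γ = 0` guarantees even
at low density — the percept `s = −2` effectively stops occurring (frozen
relative positions), and that edge is only touched again when a rare
spontaneous flip (~once per 10³ sweeps at the saturated `P(+1|+2)`)
briefly creates an opposing agent. Growth towards unity is real but
asymptotic, on time-scales far beyond 10⁴ sweeps.

With immediate forgetting (`γ = 1`) the memory resets every interaction
and all tracked probabilities stay at chance to within sampling noise,
as they must.

A learning run also shows a *behavioural* transient absent from
fixed-disposition runs: the regime label over the first 500 sweeps
differs from the label over the final 2000 sweeps in most learning seeds
(8/10 at `N = 40`) but few fixed ones (3/10), because the response
probabilities, not just the spatial configuration, are still
equilibrating.

One further observation: the kernel-estimated diffusion at the origin is
much flatter in `N` than the neutral-policy `1/(2N)` scaling —
`D(0; N=70)/D(0; N=10) ≈ 0.40` at `d = 30` — though not constant; the
value depends on the estimation convention and on what one takes as the
unit of time, so it is reported here as an observation rather than
asserted as an invariant.

# Numerical and testing choices

* Kernel rows are exact multinomial estimates; row-stochasticity is
  checked to 1e−9 and the mirror symmetry `P(z′|z) = P(−z′|−z)` to four
  Monte-Carlo standard errors.
* Probability normalisation is asserted to 1e−12; the mean-field closed
  forms at `d = 0` to machine precision.
* Degenerate inputs: an identically-zero drift returns an empty
  fixed-point table flagged degenerate (the whole line is fixed);
  empty kernel rows and too-short trajectories raise errors rather than
  returning silent zeros.
* Problem sizes: the test-suite simulations use 10⁴ kernel samples per
  grid row for the headline fixed-point checks, 1500–4000 per row for
  property checks, trajectories of 2×10⁴ sweeps for empirical
  Kramers–Moyal estimates, and 10-seed ensembles for regime and learning
  statistics; these sizes put Monte-Carlo error comfortably below the
  asserted tolerances while keeping the whole suite around a minute of
  compute.

# What the simulations do and do not show

The generator *is* the model: every test input is produced by the seeded
simulator itself, under the standard study conditions above. Passing
tests therefore demonstrate the internal consistency of the model and
its collective-level derivations — not that real locusts learn their
interaction rules this way, nor that the percept space, reward scheme or
one-dimensional geometry capture field conditions. Known limitations:
the arena is one-dimensional with unit speeds and no exclusion; percepts
are heavily coarse-grained; rewards are immediate and binary; the
fixed-order asynchronous schedule is one of several defensible
conventions (a synchronous variant is deliberately out of scope); and
the uniform-position conditioning of the kernel ignores the
position–heading correlations discussed above, which matter at high
decisiveness and low density.
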