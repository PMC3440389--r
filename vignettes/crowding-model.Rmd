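---
title: "Crowding as negative feedback in trail-recruiting foragers: the model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crowding as negative feedback in trail-recruiting foragers: the model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antcrowd)
```

## The question the model addresses

Mass-recruiting ants such as *Lasius niger* advertise food with a trail
pheromone. The recruitment response to the trail is strongly non-linear, so
small early differences between two equal options amplify: colonies often end
up exploiting one of two identical feeders almost exclusively ("symmetry
breaking") and, once committed, are notoriously slow to move to a better
feeder that appears later. `antcrowd` implements a spatially explicit
agent-based model of this system in which a second, negative feedback —
crowding at the food — counteracts the positive feedback of the trail. Two
questions drive every analysis in the package:

1. In a **stable environment** (two identical patches), does crowding prevent
   symmetry breaking?
2. In a **changing environment** (a superior patch opens mid-trial), does
   crowding let the colony reallocate its foragers quickly — even when the
   old trail has not decayed?

## World

The arena is a T-maze of unit cells: a 5 × 4 nest block, a 24 × 5 stem, a
crossbar carrying an 11 × 4 arm on each side, and a 4 × 4 food patch at each
arm's distal end. One cell is one body length; one time step is roughly one
second, chosen so that the walk home from a patch takes about 40 steps at a
speed of one cell per step. Runs last 5400 steps (~90 min). The crossbar
overlaps the top four rows of the stem — the arms attach to the *sides* of
the stem head. This junction realisation matters: the returning foragers'
trails from the two arms then cross the stem's central climb column with
lateral separation, so an outbound trail-follower's forward sensing cone can
compare the left and right lanes where they fork (see *Pheromone diffusion*
below for why that comparison needs help from the field itself). Junction
cells belong to the stem region, so the per-arm pheromone summaries are
symmetric by construction.

Two static/dynamic fields live on the cells:

* **nest scent**, `100 - d` with `d` the Euclidean distance between cell
  centres, maximal at the nest centre — the homing cue for food-laden ants;
* **pheromone**, deposited by successful foragers and decaying exponentially.

## Agents

Each of the (default) 500 agents carries a continuous position, one of 8
compass headings, and one of six behavioural states:

| state | behaviour | exit |
|---|---|---|
| idle | waits in the nest | leaves with p = 0.002/step |
| searching | random walk; follows trail when detected | feeds, or turned away |
| feeding | stationary at a patch | after 60 steps, crop full |
| recruiting | homes on nest scent, deposits 60 units/cell | reaches the nest |
| unloading | stationary in the nest | after 60 steps, idle |
| dissatisfied | random walk, blind to pheromone | enters a patch with a free slot |

Movement is off-lattice: every step has length exactly one cell in one of the
8 directions (multiples of 45°). Directed movement (trail following, homing)
samples the three cells one step ahead at 0°/±45° of the heading and turns
toward the walkable cell with the greatest field value — above the detection
threshold of 0.05 units for pheromone; nest scent needs no threshold. Ties
break uniformly at random; the heading updates to the movement direction.
Random walks draw uniformly from the admissible directions (those whose
destination stays on the maze); a fully boxed-in agent would reverse its
heading, which cannot happen on the default maze.

**Crowding** is all-or-nothing: each patch has a threshold (8, 24, 72 or 216
agents feeding simultaneously, calibrated as ~8 ants per feeding hole of the
corresponding laboratory feeders). An agent *entering* a patch region with a
free slot starts feeding; entering a full patch turns it dissatisfied. The
trigger is the boundary crossing: an agent already inside the region when a
slot frees (or when the patch opens) must leave and re-enter. Dissatisfied
agents random-walk without reading or laying trail until they enter any open
patch with capacity — this trail-blind wandering is the mechanism that
carries foragers from a crowded patch to the alternative one.

Two documented variants are exposed but off by default: `nest_resets`
(searching/dissatisfied agents re-idle on re-entering the nest) and
`diss_off_patch` (dissatisfaction ends on leaving the patch region). The
first weakens small-colony switching below what the reference analyses show;
the second abolishes switching altogether, because every turned-away forager
is immediately recaptured by the trail to the crowded patch. Both were
rejected as defaults on those grounds.

## Scheduling

Within a time step the state groups are updated asynchronously in sequence —
idle, searching, feeding, dissatisfied, recruiting, unloading (or exactly
reversed, via `update_order`) — and each agent acts at most once per step, so
an agent whose state changes mid-step is not updated again by a later group.
This makes the forward and reversed orders statistically indistinguishable,
which the robustness test asserts. After all agents have acted, deposits
having landed immediately on entry to each cell, the field diffuses and then
decays once: `C(t) = C(t-1) * (100 - r)/100` with `r` in percent per step.
Recording happens last, so every reported series respects the crowding
ceiling and state conservation at every step.

## Pheromone diffusion

The decay law above is the printed one; the only field process added to it is
a small per-step diffusion: a fraction `diffusion_rate` (default 0.05) of
each cell's pheromone spreads equally toward its 8 neighbours, shares aimed
at non-walkable cells being lost at the walls. The reason is structural, not
cosmetic. With a strictly cell-local field, the two arms' return lanes merge
into single shared cells on the stem axis, and a follower heading up the stem
can never hold both arms' lane cells in one ±45° sensing cone: its fork
choice degenerates into a coin flip no matter how unequal the trails are.
Measured consequence: symmetry breaking at the weakest crowding erodes to a
majority share of ~0.63 over a run, instead of the strong sustained breaking
the system is known for. A modest lateral spread lets the field itself carry
a cross-trail gradient, and the same greedy cone then resolves the fork in
proportion to trail strength (majority share ~0.99). The rate was fixed once
against the model's own calibration anchor — at the default evaporation rate
(r = 0.4) an established trail should take roughly 2700 steps (~45 min) to
fall below the 0.05 detection threshold — which the measured peak trail
strength of ~1500–2400 units reproduces. Trail-following models in
cell-based simulation environments conventionally diffuse the chemical each
tick; treat `diffusion_rate = 0` as the strictly local variant if you want
to reproduce the coin-flip behaviour.

## Experiments and summaries

* `experiment_stable()` — both patches open at step 0 at the same threshold.
  Per replicate, the *majority patch* is the one ahead at step 600; a run is
  summarised by the mean proportion of feeders at that patch and by the
  *symmetry index* (mean |p1 − p2| over time points with any feeders).
* `experiment_changing()` — patch 1 opens at 0, patch 2 at step 900 with
  three times the capacity (8v24, 24v72, 72v216). The *crossing time* is the
  first step from which the across-replicate mean count at patch 2 exceeds
  patch 1 for 60 consecutive steps (one simulated minute; the persistence
  window suppresses single-step noise, and the same rule applies to the
  per-arm pheromone sums). Per-run crossings are also reported; the
  headline summaries use the crossing of the averaged series.
* `sensitivity_sweep()` — one-parameter grids over colony size, decay rate,
  geometry multipliers, or the routed-dissatisfied probability, with 10
  replicates per point (30 for headline experiments). A grid point counts as
  *switched* only if the mean series shows a sustained crossing **and**
  patch 2 holds the majority of feeders over the final 500 steps; the second
  condition discards noise crossings of near-zero counts in very small
  colonies.

Replicates use seeds `seed_base + replicate`, so every experiment is
bit-reproducible; identical configuration and seed give identical output.

## What the model reproduces, and what it does not

At the reference settings the package reproduces: the monotone weakening of
symmetry breaking with crowding (majority share ~0.52 at threshold 8 versus
~0.99 at 216); rapid reallocation at 8v24 with the forager crossing near
1000 steps, strictly before the branch-pheromone crossing near 1100; no
reallocation at 72v216 with 500 agents; switching without any pheromone
decay; a minimal switching colony of ~200 agents at 8v24 and ~1750–2250 at
72v216; slower switching when routed dissatisfied foragers prefer the nest;
and the trail-decay calibration (~2600 steps at r = 0.4, under 600 steps at
r = 2).

Two reference findings do **not** reproduce under the adopted rules, and the
package reports them as measured rather than forcing them. First, the
regression of the forager switch time on log decay rate is essentially flat
here: the switch is carried by trail-blind dissatisfied walkers, so
evaporation speed moves the *pheromone* crossing (negative slope, R² ≈
0.65–0.8) but not the forager crossing. A strong decay dependence of the
forager switch would require the switch to be gated by trail routing, which
contradicts the observation — reproduced here — that foragers cross before
the pheromone does. Second, with arms six times longer the colony still
switches in this implementation, because sticky wanderers eventually
accumulate near the distant patch; under the `nest_resets` variant the
long-arm failure to switch does reproduce, at the cost of the small-colony
results. These tensions are documented in the analysis scripts and left
visible in the test suite.

## The synthetic trial generator

`gen_stable()` and `gen_changing()` produce two-feeder count series shaped
like the laboratory protocols (24 counts at 5-min intervals; 45 counts at
2-min intervals with the second feeder appearing around the 8th count) with
known ground truth, so that every statistic — proportions, symmetry index,
sustained crossing, bias chi-square, one-sample t, Holm adjustment, the
log-decay regression — is testable without the simulator. Overdispersed
counts come from a negative-binomial total split binomially at the planted
bias; the changing generator plants an exact switch point, guarantees
feeder 2 is absent before onset, bounds its jitter so the planted ordering
survives, and inserts single-point pre-switch blips that any persistence
window of at least 2 points must reject. These generators emulate the
*structure* of trial data, not the behavioural dynamics of real colonies:
passing recovery tests shows the statistics are implemented correctly, not
that the biological model is right.

## Numerical and reproducibility notes

* Problem sizes: headline experiments use 30 replicates of 500 agents for
  5400 steps; sweeps use 10 replicates per grid point; the long-stem sweep
  runs 19400 steps against a 14000-step opening delay.
* All randomness flows through R's RNG: a single integer seed fixes a run
  bit-exactly, and derived seeds stay well below 2^31.
* Exponential decay is applied multiplicatively each step; after k undisturbed
  steps the field equals its closed form to within 1e-9, which the tests
  assert.
* Degenerate inputs fail fast with named errors: zero-width geometry,
  negative rates, probabilities outside [0, 1], routed mode without its
  probability, unknown configuration keys.
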