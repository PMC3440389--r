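# antcrowd

Agent-based simulation of collective foraging in mass-recruiting ants, built
around the interplay of two feedbacks on a T-maze with two food patches:

* **positive feedback** — successful foragers deposit trail pheromone on
  every cell they cross on the way home, recruiting and directing nestmates;
* **negative feedback** — each patch admits at most a fixed number of
  simultaneous feeders (the *crowding threshold*); surplus arrivals are
  turned away and wander off trail-blind ("dissatisfied").

The package is for behavioural ecologists and modellers studying collective
decision-making: it reproduces, in one seeded and fully scripted pipeline,
how crowding prevents *symmetry breaking* between two identical food sources
and how it enables a colony to *reallocate* its foragers to a superior source
that appears after foraging is underway — even with zero pheromone decay.

## The model in brief

Agents cycle through six states (idle → searching → feeding → recruiting →
unloading, with *dissatisfied* the crowded-out branch). Searching agents
sample the three cells ahead at 0°/±45° of their heading and turn toward the
largest pheromone amount above a detection threshold (0.05 units), otherwise
they step uniformly at random; recruiters home the same way on a static nest
scent `100 − d(X, X_nest)` while laying `c = 60` units per cell. The field
evaporates each step by the exponential rule

    C_i(t) = C_i(t − 1) × (100 − r) / 100,      r = 0.4 %/step by default,

with a small lateral diffusion (5 %/step to the 8 neighbours) that carries
the cross-trail gradient the forward sensing cone needs at the maze junction.
Defaults: 500 agents, 5400 steps (one step ≈ 1 s), drinking and unloading 60
steps each, per-agent nest-leaving probability 0.002/step, crowding
thresholds from {8, 24, 72, 216}. See the methods vignette
(`vignettes/crowding-model.Rmd`) for the full account and every design
decision.

## Worked example

A changing environment: patch 1 (8 feeding slots) opens at step 0, patch 2
(24 slots) at step 900.

```r
library(antcrowd)

cfg <- sim_config(thresholds = c(8, 24), patch2_delay = 900, seed = 1)
run <- run_simulation(cfg)
run
#> <ant_run> 5400 steps, colony 500; final feeding 2/24, final arm pheromone 3084/18900

s <- run$series
s[c(600, 1000, 2000, 5400), c("step", "n1", "n2")]
#>  step n1 n2       # 8/0 -> 8/8 -> 8/24 -> 2/24
crossing_time(s$n1, s$n2, persistence = 60, times = s$step)
#> [1] 923
```

Patch 1 saturates at its 8-slot ceiling, the superior patch fills after it
opens, and the colony's feeding majority crosses over at step 923 in this
run. The headline analyses average 30 such replicates:

```r
reps <- run_replicates(cfg, n_runs = 5, seed_base = 1)
switch_summary(reps)
#> $crossing_time_agents
#> [1] 1015
#> $crossing_time_pheromone
#> [1] 1097
#> $switched
#> [1] TRUE
```

The forager crossing (step 1015) precedes the branch-pheromone crossing
(step 1097): the foragers reallocate before the trail balance flips, so the
pheromone pattern is a consequence, not the cause, of the switch.

The numbered scripts under `analysis/` run the full study: stable-environment
symmetry breaking across crowding levels (`01`), changing-environment
switching with the zero-decay control (`02`), the decay-rate sweep and
log-decay regression (`03`), colony-size / routing / geometry sensitivity
(`04`), and the trial-statistics pipeline on synthetic data (`05`). Each
writes tidy CSVs under `results/`.

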