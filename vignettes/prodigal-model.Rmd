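---
title: "The damage-repair model behind prodigal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The damage-repair model behind prodigal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prodigal)
```

## The question the simulator asks

When an environment improves — CO~2~ or nutrient enrichment raising the
ceiling on how fast a microbial cell can divide — can a population keep the
faster division rate over hundreds of generations? **prodigal** simulates an
asexual population in which the answer hinges on cellular damage: faster
metabolism produces more damage (oxidised components, malfunctioning
proteins), damage is partly transmitted to daughters, and damaged offspring
are more likely to be nonviable. Selection for fast dividers and selection
against damage-laden lineages pull in opposite directions, and the balance
can force evolved growth rates back toward — even below — their ancestral
values ("Prodigal Son" dynamics), unless the population escapes by
tolerating damage, repairing it more cheaply, or producing less of it.

## State variables and deterministic core

Each cell carries two numbers: a heritable growth rate $g$ (its per-generation
reproduction propensity, clamped to the environment's permitted range
$[0, g_{\max}]$) and a damage load $D \ge 0$.

**Damage dynamics.** Damage accrues with growth and is removed by repair,

$$\frac{dD}{dt} = g\,D_{\max} - R(g)\,D,$$

where $t$ is time in generations, $D_{\max}$ the damage rate (default 5),
and $R(g)$ the repair rate.

**Repair-growth trade-off.** Resources allocated to growth are unavailable
for repair. Repair declines linearly from $R_{\max}$ (all resources to
repair; default 5) to $R_{\min}$ over a reference growth range $g_{\mathrm{ref}}$:

$$R(g) = R_{\max} - s\,(R_{\max} - R_{\min})\,\frac{g}{g_{\mathrm{ref}}},
  \qquad R \text{ clamped to } [R_{\min}, R_{\max}],$$

with slope $s = 1$ by default. The reference range is a property of the
cell's *physiology*, not of the current environment: a population adapted to
$g_{\max} = 1$ that suddenly finds itself allowed to grow at rate 2 is
already devoting everything beyond $g = g_{\mathrm{ref}} = 1$ to growth, so its
repair stays pinned at $R_{\min}$ there. This is what makes enrichment
dangerous: the permitted range doubles but the repair line does not stretch
with it. A population *native* to the richer environment (the
`constant_2.0` control) has $g_{\mathrm{ref}} = 2$ instead. Modelling the
trade-off on $g / g_{\max}$ of the current environment would make enrichment
strictly more permissive at every growth rate and no return to ancestral
growth rates could ever occur.

**Equilibrium damage.** Setting $dD/dt = 0$ gives
$D_{\mathrm{eq}}(g) = D_{\max}\, g / R(g)$: zero for a non-growing cell,
rising steeply as $R(g)$ approaches $R_{\min}$.

**Inherited damage and the relaxation time.** A daughter starts with her
parent's damage $D_p$ (optionally a fraction of it, `inheritance`), then her
own metabolism reshapes it over a relaxation time $\Delta t$:

$$D_{\Delta t} = D_{\mathrm{eq}}(g) + \left(D_p - D_{\mathrm{eq}}(g)\right)
  e^{-R(g)\,\Delta t}.$$

$\Delta t = 0$ means damage is fully parental; $\Delta t \to \infty$ means
it is fully determined by the daughter's own growth. The exponent is
negative — exponential relaxation *toward* equilibrium — because that is the
only sign under which both limits hold; the dynamics are the closed-form
solution of the damage ODE over a window of length $\Delta t$.

**Mortality.** An offspring with damage $D$ is nonviable with Hill
probability

$$V(D) = \frac{D^\alpha}{K^\alpha + D^\alpha},$$

half-maximal at the tolerance threshold $K$ and approaching a step function
as the steepness $\alpha$ grows (the sweeps use $\alpha \in \{2, 4, 10\}$).
`mortality_probability()` uses the ratio form $(D/K)^\alpha / (1 + (D/K)^\alpha)$
so large $\alpha$ cannot overflow, and $K = \infty$ disables mortality
entirely (the neutral control).

**Deterministic prediction.** When damage is entirely offspring-determined,
a lineage growing at $g$ produces viable offspring at rate
$(1 - V(D_{\mathrm{eq}}(g)))\,g$. Its maximiser over $[0, g_{\max}]$
(`predicted_equilibrium_growth()`, coarse grid + `optimize()`) is the
reference line drawn on trajectory plots.

## The stochastic generation loop

Generations do not overlap and population size $N$ is fixed. Each
generation:

1. a parent is drawn with replacement, with probability proportional to its
   growth rate;
2. the offspring's growth rate is mutated and clamped to $[0, g_{\max}]$;
3. its damage is computed from the inherited load and its own growth via the
   relaxation formula;
4. with probability $V$ of that damage the offspring is discarded and the
   *selective death* counter increments; otherwise it fills one of the $N$
   slots.

Sampling continues until all $N$ slots are filled. Viability is evaluated on
the *offspring's* projected damage — the ordering under which $\Delta t$
actually modulates selection. If a generation cannot be filled within a cap
of attempts (default $1000\,N$), the run aborts with a `prodigal_extinction`
condition: the regime where adaptation costs more deaths than the population
can absorb is reported, not silently truncated. The loop is implemented in
compiled code using R's own RNG, so a run is bit-reproducible from
`set.seed()` on any platform.

**Mutation kernel.** The mutation parameter is 0.05. The default reading is
a Gaussian perturbation with standard deviation 0.05 applied to every
offspring — continuous-trait mutation, which supplies enough variance for a
population to traverse the enriched growth range within 1000 generations. A
second mode (`mutation_mode = "rare"`) mutates each offspring with
probability 0.05 by a fixed-size effect of random sign; it produces much
smaller standing variation and correspondingly slower adaptation, and is
provided for sensitivity analysis rather than as the default.

## Parameters that matter, and their defaults

| parameter | default | meaning |
|---|---|---|
| `g_max` | 1 (ancestral), 2 (enriched) | permitted growth range |
| `D_max` | 5 | damage produced per unit growth rate |
| `R_max` | 5 | repair with full allocation |
| `R_min` | 0.05 | repair floor (see below) |
| `repair_slope` | 1 (0.25 cheap repair) | cost of growth in repair units |
| `g_ref` | `g_max` at construction | growth range the physiology is adapted to |
| `K` | $D_{\mathrm{eq}}(g_{\mathrm{ref}})/2$ | damage at 50% offspring mortality |
| `alpha` | 4 | Hill steepness |
| `delta_t` | 0.1 | offspring control over damage |
| `mutation_scale` | 0.05 | mutation kernel s.d. |
| `N`, generations, replicates | 1000, 1000, 100 | sweep sizes |

**Anchoring $K$.** Damage tolerance evolves in the environment a population
is adapted to and then stays fixed: $K = D_{\mathrm{eq}}(1)/2$ for anything
with ancestral physiology ($g_{\mathrm{ref}} = 1$), $D_{\mathrm{eq}}(2)/2$
for the natively-rich control. The damage-tolerance escape scenario raises
the divisor's value to $D_{\mathrm{eq}}(1)/1.1$ in the enriched environment
only.

**Choosing $R_{\min}$.** The repair floor is the one constant with no
canonical value, and it controls everything: $K = D_{\max}/(2 R_{\min})$,
and the "damage wall" — the growth rate where $D_{\mathrm{eq}}(g)$ crosses
$K$ — sits at $g_{\mathrm{wall}} = R_{\max} g_{\mathrm{ref}} /
(R_{\max} + R_{\min})$ for $s = 1$. The default $R_{\min} = 0.05$ places the
wall at $0.99\,g_{\mathrm{ref}}$, so that a population in a stable
environment equilibrates just below its growth cap — the plateau reflecting
only the baseline cost of repair (pooled over the $\Delta t$ and $\alpha$
grids: $\approx 0.91$ at $g_{\max} = 1$ and $\approx 1.85$ at
$g_{\max} = 2$, the values the acceptance script recomputes). Larger floors
(e.g. $R_{\min} = 1$) pull the wall down to $0.83\,g_{\mathrm{ref}}$ and
stable-environment growth down to $\approx 0.7$; the deterministic
`predicted_equilibrium_growth()` curve makes this dependence easy to explore
before running anything stochastic.

## Scenarios

`build_scenario()` constructs (ancestral, enriched) parameter pairs:

* **reference** — only $g_{\max}$ changes ($1 \to 2$); repair, damage rate
  and $K$ are ancestral physiology carried into the new environment.
* **damage_tolerance** — enriched $K$ raised from $D_{\mathrm{eq}}(1)/2$ to
  $D_{\mathrm{eq}}(1)/1.1$.
* **cheap_repair** — enriched repair slope lowered from 1 to 0.25 (e.g.
  resources freed by down-regulating carbon-concentrating machinery).
* **damage_reduction** — enriched damage rate lowered from 5 to 2.
* **constant_1.0 / constant_2.0** — single stable environment, natively
  adapted; controls for what each environment supports.

`run_enrichment()` equilibrates 1000 generations under the ancestral
parameters, zeroes the death counter, switches instantaneously, and evolves
1000 generations more. Constant scenarios simply evolve from the seeded
state ($g_0 = 0.5$ with its equilibrium damage) — their recorded generations
*are* the equilibration. Selective deaths are therefore always post-switch
counts.

## Sweeps and reproducibility

`run_sweep()` crosses scenarios with the $\Delta t$ grid
$\{0.01, 0.05, 0.1, 0.4, 0.8, 1.0\}$ and $\alpha \in \{2, 4, 10\}$, running
(by default) 100 independently seeded replicates per cell. Every replicate's
seed is pre-derived from the master seed in fixed grid order, so results are
independent of execution order and a rerun is byte-identical. Replicate
extinctions are recorded in a status column, not raised. Aggregation
reports, per cell, the across-replicate mean and variance of the final
population means (the headline "mean ± variance" convention) *and* the mean
within-population variances, clearly separated.

## What the tests do and do not show

The unit and property suite checks the deterministic core against an
independent ODE integration (`deSolve`), the limits of the relaxation
formula, exact Hill properties, Monte-Carlo consistency of the compiled
engine with the R-level formulas, the geometric-trials expectation for
reproduction attempts, fixed population size, bit-identical reruns, and the
qualitative orderings (growth declining in $\Delta t$; every escape scenario
out-growing the reference at $\Delta t = 0.1$; damage-tolerant populations
carrying more damage; cheap repair cutting damage several-fold). Stochastic
ordering tests run scaled down (typically $N = 300$, 400 + 400 generations,
6–8 replicates); the headline equilibria are checked at the full
$N = 1000$, 1000-generation, 10–20-replicate sizes in the acceptance tests
and recomputed by `scripts/acceptance.R`.

The generator emulates none of the biology beyond its two traits: there is
no plastic response, no competition between genotypes beyond reproduction
weighting, no environmental fluctuation, no explicit genetics. Passing
tests therefore show that the *model* behaves as specified, not that real
populations will.

## Numerical choices and degenerate inputs

* Growth is clamped to $[0, g_{\max}]$ after mutation; repair to
  $[R_{\min}, R_{\max}]$. $R_{\min} > 0$ is enforced so equilibrium damage
  stays finite.
* Mortality uses the overflow-safe ratio form; $D = 0$ gives $V = 0$
  exactly, $D = K$ gives $V = 0.5$ exactly.
* An all-zero-growth population raises a distinct `prodigal_degenerate`
  error (it cannot reproduce under the model's own logic) rather than being
  resampled uniformly.
* The optimiser for the predicted equilibrium brackets on a 2001-point grid
  before `optimize()`, and never returns less than the best grid value.
* Replicate seeds are drawn from a temporarily-seeded stream that restores
  the caller's RNG state.

## Known limitations

Two behaviours of this implementation deserve flagging. First, with full
damage inheritance, lineage damage relaxes toward $D_{\mathrm{eq}}$ of the
*current* growth rate at rate $\approx R\,\Delta t$ per generation; at small
$\Delta t$ this drift is nearly invisible to selection (offspring damage is
almost perfectly heritable), so over 1000 generations fast-growing
populations accumulate substantial damage loads and a correspondingly large
chronic selective-death count. Mean damage and death counts in the
fast-growth regimes are therefore much larger than the near-zero damage a
reader might expect from the growth trajectories alone, and death counts are
*not* monotone in $\Delta t$. Second, because repair beyond
$g_{\mathrm{ref}}$ is clamped at a small $R_{\min}$, the damage of
above-wall mutants relaxes slowly even at $\Delta t = 1$; such lineages
transiently escape viability selection, which keeps the reference scenario's
collapsed growth at high $\Delta t$ slightly *above* the stable-environment
pooled mean rather than below it. Both are direct consequences of the
relaxation bookkeeping; the qualitative collapse of growth with increasing
offspring control of damage, and every escape-strategy ordering, are robust
to them.
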