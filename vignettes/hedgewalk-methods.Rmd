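---
title: "Movement of central-place-foraging pollinators in hedgerow-structured landscapes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement of central-place-foraging pollinators in hedgerow-structured landscapes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hedgewalk)
```

## The model

`hedgewalk` is a spatially-explicit individual-based simulation of how a
central-place-foraging pollinator (a bumblebee or solitary bee nesting at a
fixed site) moves through an agricultural landscape, and of how two common
agri-environment manipulations — converting whole fields to wild set-aside,
and removing hedgerows between fields — change that movement.

### Landscapes

A landscape is a rectangular grid of square cells partitioned into
agricultural fields by a grid-based Voronoi tessellation: `n_fields` seed
points are placed uniformly at random on distinct cells, and every cell
joins the field of its nearest seed (Euclidean distance between cell
centres; ties go to the lowest field id, which makes the assignment
deterministic and independent of seed ordering). Field boundaries carry the
wild habitat: hedgerow cells form single-thickness strips between fields,
and everything else is crop monoculture. The pollinator's nest is a
uniformly random hedgerow cell — cultivated land is assumed too disturbed
to host a nest — and every simulated foraging walk starts there.

**The boundary rule.** Marking every cell that has *any* differing
neighbour puts wild strips on both sides of each boundary, i.e. two cells
thick. We instead lay one strip per field–field interface, on its lower
field-id side: a cell is wild iff some neighbour in its 3×3 neighbourhood
belongs to a field with a higher id. The 8-cell neighbourhood matters:
with an orthogonal-only scan, boundaries that run diagonally decompose
into isolated single cells with no edge-sharing wild neighbour, which
breaks the corridor topology (and would strand habitat-confined walkers,
see below). Under the 3×3 rule every hedgerow cell shares an edge with
another hedgerow cell; strips are one cell wide along axis-aligned
boundaries and form minimal edge-connected staircases along diagonal ones.

The wild network is usually one connected component. The exception is
genuine, not numerical: a field tucked into a grid corner that touches
only one other field produces a standalone hedge arc running border to
border, disconnected from the rest of the network under any one- or
two-sided marking rule. A small fraction of generated landscapes carry
such an arc; `wild_components()` reports the component count so they can
be flagged.

### Movement

The walker performs a habitat-biased correlated random walk on the grid.
Its state is its cell and its heading (the absolute direction of the move
that brought it there). Relative to the heading the four orthogonal
neighbours are forward, right, backward and left, with unadjusted
probabilities

$$p_F, \quad p_S \text{ (each side)}, \quad p_B, \qquad
  p_F + p_B + 2 p_S = 1 .$$

Rather than choosing the triple freely, experiments use the one-parameter
family

$$p_S = \frac{1 - p_F}{3} + \frac{v (1 - p_F)}{6}, \qquad
  p_B = 1 - p_F - 2 p_S,$$

with $v \in [0,1]$: at $v = 0$ the non-forward mass splits evenly over the
three remaining directions, at $v = 1$ backward moves vanish.

Habitat preference enters through the switching reduction $r \in [0,1]$.
With the walker on a cell of habitat $c_{\text{current}}$ and the
neighbouring cell in direction $i$ holding habitat $c_i$, the adjusted
preference is

$$m_i = \begin{cases} p_i & c_i = c_{\text{current}} \\
                      r\,p_i & c_i \ne c_{\text{current}}, \end{cases}$$

and the realised step probabilities are $a_i = m_i / \sum_j m_j$. Thus
$r = 1$ is a habitat-neutral walk and $r = 0$ a strict specialist that
never leaves the habitat type it starts in.

Each trajectory of $T$ timesteps is summarised by three statistics: the
maximum Euclidean distance from the nest over the $T$ post-move positions
(grid units), the number of habitat switches between consecutively
occupied cells, and the proportion of the $T$ post-move positions on wild
cells.

### Conventions the movement model needs but the biology does not fix

* **Initial heading** — drawn uniformly from the four absolute
  directions (reported per walk as `init_heading`).
* **Grid border** — off-grid directions get preference 0 and the
  remaining preferences are renormalised; the walker cannot leave the
  grid. At the default 1000×1000 scale with interior nests the border is
  rarely touched; `border_steps` counts timesteps spent on a border cell
  so runs where this matters are visible.
* **Completely blocked walker** ($\sum_i m_i = 0$, possible only for
  $r = 0$ in degenerate geometry) — stays in place for the timestep,
  heading unchanged; the timestep still counts in `prop_wild`.
* **`prop_wild` denominator** — the $T$ post-move positions; the nest
  cell at $t = 0$ is not counted, keeping all three statistics functions
  of the same $T$ movements.
* **Switch counting** — habitats of consecutively occupied cells, so a
  stay-in-place step can never register a switch.

## Landscape manipulations

**Set-aside conversion** picks not-yet-converted fields uniformly at
random and fills all their cells with wild habitat; the field map is
untouched, so conversion is reversible bookkeeping on habitat only and
cumulative across a schedule (0, 5, …, 50 fields by default).

**Hedge removal** first decomposes the basal corridor network into
individual hedges: a hedge is the strip of hedgerow cells between one
pair of adjacent fields; a wild cell belongs to hedge $(A, B)$ iff its own
field is $A$ or $B$ and exactly the ids $\{A, B\}$ appear in its 3×3
neighbourhood. Cells where three or more fields meet are the network's
junction nodes: they belong to no hedge and are never removed, so removal
deletes edges of the corridor graph but not its vertices. Scheduled
removals (0, 4, …, 40 hedges by default) turn member cells to crop,
cumulatively. If removal converts the nest cell itself, a fresh nest is
drawn from the remaining wild cells (counted in the run's `nest_redraws`
attribute); the walker is never left nesting in crop.

## Experiment protocols

All protocols share a repeated-measures design: each replicate
*environment* gets its own landscape, nest and nuisance-parameter draws,
and the systematically varied quantity is swept within the environment —
one fresh walk per level. Defaults are the full study conditions: 1000
environments, 1000×1000 cells, field count uniform on [101, 200], and
$T = 1000$ timesteps.

| protocol | sweeps | per-environment draws |
|---|---|---|
| `run_model1` | $p_F \in \{0.25, 0.375, \dots, 0.875\}$ | $r, v \sim U(0,1)$ |
| `run_model2` | $r \in \{(2/3)^0, \dots, (2/3)^{13}\}$ | $p_F \sim U(0.25,1)$, $v \sim U(0,1)$ |
| `run_model3` | set-asides 0, 5, …, 50 | $p_F \sim U(0.25,1)$, $v, r \sim U(0,1)$ |
| `run_model3a` | as Model 3 with $r = 0$ | records `max_distance` only |
| `run_model4` | hedges removed 0, 4, …, 40 | as Model 3 |
| `run_model4a` | as Model 4 with $r = 0$ | records `max_distance` only |

Environments that cannot support a schedule (no wild cell; fewer hedges
than the removal schedule needs) are redrawn and counted in the `redraws`
attribute, keeping the number of environments fixed.

`run_sensitivity()` crosses one axis ($p_F$ over 0.1–0.9; $p_S$ over
0–0.45 with $p_F = (1 - 2 p_S) \cdot U(0,1)$, which keeps $p_B \ge 0$ by
construction; $r$ over 0–0.9; or the seeded field count) with either
manipulation schedule, replicated over randomised draws of the remaining
parameters, and reports the mean and standard deviation of the three
statistics per grid point. The field-count axis levels
$\{50, 100, 150, 200, 250\}$ are this package's choice (no canonical set
exists): they bracket the default [101, 200] range symmetrically on the
1000×1000 grid while keeping the 50-field set-aside schedule feasible at
the lower end.

**Reproducibility.** A master seed expands into named substreams: one
seed per environment, and within an environment one per assay level and
one per manipulation draw. Identical (configuration, seed) pairs give
byte-identical CSV output, and adding levels to a sweep does not perturb
the draws of existing levels.

## Statistical analysis

`fit_trend_test()` mirrors the study's analysis: each movement statistic
is modelled as a linear mixed model with the swept variable as a
categorical fixed effect and the environment as a random intercept, and
the full model is compared against the intercept-only null by a
likelihood-ratio test, $\chi^2 = 2(\ell_{\text{full}} -
\ell_{\text{null}})$ on $k - 1$ df. Fitting is by maximum likelihood, not
REML — REML likelihoods are not comparable across fixed-effect
specifications, so the LRT requires ML. The predictor is coded
categorical because the protocols probe discrete levels and follow up
with all-pairs comparisons. When the LRT is significant at 0.05,
single-step multivariate-$t$ ("Tukey") post-hoc contrasts from
**multcomp** map the shape of the response; if that adjustment fails
numerically the package falls back to Holm-adjusted Wald contrasts and
says so in `posthoc_method`. A response with zero variance short-circuits
to $\chi^2 = 0$, $p = 1$, flagged `degenerate`. `trend_summary()`
condenses a fitted test into the direction/strength arrow notation used
in overview tables, always returning the underlying contrast pattern so
the verbal classification can be audited rather than trusted.

## Numerical and implementation choices

* The Voronoi assignment and the walk inner loop are compiled (Rcpp); the
  test suite re-derives both with plain R oracles (a cell-by-cell
  nearest-seed scan, and a step-by-step walker built on the exported
  single-step functions that consumes the identical RNG draws, so
  trajectories match move for move).
* All randomness flows through R's Mersenne-Twister stream, including
  inside the compiled code (`unif_rand`), so `set.seed()` governs
  everything; the compiled walk consumes exactly one uniform per timestep
  plus one for the initial heading.
* Distances are Euclidean between cell centres in grid units; squared
  integer distances are compared exactly, so Voronoi ties are detected
  without floating-point hazards.
* Desk-scale runs in the tests and the acceptance script use 100
  environments on 250×250 grids (50 environments for hedge-removal
  protocols, whose hedge enumeration is the most expensive step) with the
  full $T = 1000$ walks; the field-count range stays [101, 200] so the
  0–50 set-aside schedule remains feasible, which makes scaled fields
  proportionally smaller than full-scale ones (about 20 cells across
  rather than 80).

## What the generator does and does not emulate

The synthetic landscapes reproduce the structural features the movement
model is sensitive to: convex-ish fields of realistic relative size
variation, a connected single-thickness corridor network with junctions,
and nests embedded in that network. They do not emulate real agricultural
geometry — rectangular fields, roads, watercourses, variable hedge
widths, multiple wild habitat classes, or resource quality and depletion.
Passing trend tests therefore show that the *mechanisms* (corridor bias,
set-aside percolation, corridor fragmentation) behave as described, not
that effect sizes transfer to any real landscape.

## Known limitations

* The set-aside effect on specialist range (Model 3a) is scale-sensitive.
  At desk scale the 0–50 schedule forces ≥ 101 fields onto grids a
  quarter of the full linear size, so fields are 4–8× smaller in diameter;
  early set-asides then act as two-dimensional diffusive traps that offset
  the gain from a better-connected wild network, and the slight positive
  full-scale trend attenuates to approximately zero at 100 environments.
  The corresponding acceptance test is kept at the stated scale and is
  expected to fail there; treat Model 3a conclusions as full-scale-only.
* Hedge decomposition is defined on the basal landscape; hedges that
  appear *between set-asides* after conversion are not re-enumerated (the
  protocols never combine the two manipulations).
* Behavioural realism is deliberately minimal: no state-dependence,
  memory, traplining, resource dynamics or interference between foragers.
  The framework is a substrate for adding such rules, not a prediction
  engine without them.
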