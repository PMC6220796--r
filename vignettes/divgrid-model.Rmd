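---
title: "The divgrid model: diversification under local ecological limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The divgrid model: diversification under local ecological limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divgrid)
```

## The model

divgrid simulates the diversification of a clade on a bounded square grid
of `A` cells. Each cell is a local assemblage that can hold at most `K_L`
species — the *local ecological limit*. The unit of the dynamics is the
*population*: the presence of one species in one cell. Three
continuous-time processes act on populations, each with a uniform
per-population rate:

* **speciation** (rate `lambda`): a population is relabeled as a new
  species. Sisters therefore start with disjoint ranges (point speciation),
  and a parent reduced to range zero is recorded as a *pseudoextinction*.
* **colonization** (rate `gamma`): the population attempts to copy its
  species into one of the four cardinal neighbour cells, drawn uniformly.
  The attempt is a no-op — flagged, but without effect — if the target is
  off-grid, already contains the species, or is saturated (`K_L` residents).
* **local extinction** (rate `mu`): the population is removed. A species
  losing its last population goes extinct at the same instant.

Because all three processes are per-population, the total event rate is
`N_pop * (lambda + gamma + mu)` and the system is advanced exactly with the
Gillespie algorithm: exponential waiting times at the total rate, event
kind drawn with probabilities proportional to the rates, population drawn
uniformly. A run starts with a single founder in a uniformly random cell
and ends at time `t_max`, at clade extinction, or when the cumulative
species cap `max_species` is hit (flagged as a truncation).

Diversity dependence is *emergent*: no rate depends on richness directly.
Saturated cells block colonization, newly formed species stay rare, rare
species die; the clade approaches a dynamic equilibrium below the regional
ceiling `K_R = K_L * A`, the richness reached when every cell is saturated
and every species is a singleton. With `mu = 0` that saturated all-singleton
configuration is absorbing and is reached exactly.

## Parameters

| name | meaning | units | typical values |
|------|---------|-------|----------------|
| `area` (A) | number of cells; bound on range size | cells | 16–4096 |
| `k_local` (K_L) | max species per cell | species | 1–1500 |
| `lambda` | per-population speciation rate | 1/time | 0.05, 0.08 |
| `gamma` | per-population colonization rate | 1/time | 30, 80 |
| `mu` | per-population local extinction rate | 1/time | 0–5 |
| `t_max` (T) | duration | time | 35 (100 for saturation) |
| `dispersal` | `"local"` or `"global"` | — | `"local"` |
| `max_species` | cumulative species cap | species | 384000 |

Time units are arbitrary: halving all rates and doubling `t_max` gives the
same process, so `t_max = 35` with the rate pairs above describes anything
from a large clade over tens of millions of years to a small one over a
few. The built-in scenarios (`builtin_scenarios()`) encode the study's
parameter sets, including the fixed-`K_R` triple in which `K_L` and `A`
vary jointly with `K_L * A = 4096` held constant.

## Metrics

**Richness trajectories.** Regional richness at any time is derived from
the species table (origin and extinction times); local richness and range
sizes come from the final occupancy state. `Sum(range sizes) = N_pop`
always.

**Evolutionary turnover** (`turnover_series()`): species extinctions
divided by speciation events in unit-time bins; 1 signals dynamic
equilibrium. Bins without speciations are `NA`, never 0, and undefined
values propagate as `NA` throughout the package. Whether pseudoextinctions
count in the numerator is a toggle (`include_pseudo`, default `TRUE`,
consistent with treating the relabeling of a parent's last population as
the end of that species).

**delta-r** (`delta_r()`, `delta_r_run()`): the difference in net
diversification between the second and first halves of the run,

r1 = (ln N(T/2) − ln N(0)) / (T/2),  r2 = (ln N(T) − ln N(T/2)) / (T/2),
Δr = r2 − r1,

with N the number of species alive (full view) or the number of
reconstructed-tree branches (reconstructed view, i.e. only lineages with
descendants extant at T). It is 0 under constant-rate growth and negative
under a slowdown. Two conventions are in circulation: the rate version
above (each half divided by its duration, the default here, because "net
diversification" is a rate) and the raw log-ratio difference
(`normalize = FALSE`). Both are computed by `metrics_summary()`. Note two
numerical facts that matter when comparing against published values:

* under the rate convention the first half is bounded by
  `ln(K_R)/(T/2)` because richness cannot exceed `K_R`, which caps how
  negative Δr can get (about −0.48 for `K_R = 4096`, `T = 35`);
* starting the count at a single founder makes Δr positively biased for
  small clades (for a pure-birth process the bias is about
  `0.577/(T/2)`, the Euler–Mascheroni constant from `E[ln N]`), which is
  why the package's constant-rate calibration test anchors the pure-birth
  oracle at a 50-lineage crown rather than at one lineage.

**Normalized Sackin index** (`sackin_normalized()`): the sum of tip depths
(internal nodes from root to tip) centered by its exact Yule expectation
`2n * sum_{j=2..n} 1/j` and divided by the tip count — the Yule
normalization of Blum and François. Zero in expectation under pure birth,
larger for more imbalanced trees, topology-only, and comparable across
tree sizes. Undefined (`NA`) below two tips.

**Trees** (`build_full_tree()`, `reconstructed_tree()`): budding topology —
the parent's branch runs through each speciation node unbroken, the
daughter branches off. The full tree has one tip per species ever created;
the reconstructed tree keeps only lineages ancestral to extant species,
suppressing unary nodes, and is ultrametric. The root of the reconstructed
tree sits at the crown (first divergence among surviving lineages); the
stem back to time 0 is kept as the `root.edge`. An extinct clade prunes to
an explicit empty-tree object, and a sole surviving lineage to an explicit
single-lineage object; both serialize or refuse with clear messages.

## Design choices

* **Off-grid colonization targets are no-ops.** The direction is drawn
  first; an invalid target wastes the event. This keeps the per-population
  colonization propensity uniform, which the total-rate formula requires.
  The alternative (redrawing) would silently raise effective colonization
  rates at boundaries.
* **Global dispersal** draws the target uniformly from *eligible* cells
  (species absent, below `K_L`), no-op when none exist. The variant that
  draws uniformly from all cells and no-ops on ineligible targets is
  available as `global_uniform = TRUE`.
* **Pseudoextinction counts as species extinction** in recorded events and
  (by default) in turnover, matching the degenerate one-cell limit where
  every speciation implies the parent's extinction. The toggle exists
  because the convention is not forced by the model.
* **Species identities** are monotone integers; the parent keeps its id
  and origin time through speciation, the daughter gets a fresh id aged
  from the event.
* **Seeds.** One seed per run (`sim_run(seed=)` sets R's RNG; the compiled
  engine draws from the same R RNG stream). Scenario replicate `i` uses
  `master_seed + i`; the scheme is recorded in manifests.
* **Replicates ending in clade extinction** are counted and reported, but
  excluded from tree-based aggregates, which require a surviving tree.
* **Coordinates** are 0-based `(row, col)` on a row-major grid; a
  non-square grid can be forced with `dims` (used by the oracle's 1x2
  worlds).

## The exact oracle

For tiny systems the model's master equation is solved exactly
(`enumerate_states()`): all configurations reachable from the founder are
enumerated with species labels canonicalized away (the model is neutral),
transition rates assembled into a sparse generator, mean extinction times
obtained by a linear solve and transient distributions by the matrix
exponential. No-op events never appear as transitions. The test suite uses
it to verify the stochastic engine distributionally: clade lifetimes on a
1x2 grid against the exact absorption time, and the full state
distribution at `t = 1` against the matrix exponential, for both the
compiled engine and the pure-R reference stepper. On a 1x1 grid the
absorption time is `1/mu` exactly, because speciation only relabels and
colonization is always off-grid.

## What the simulator does and does not emulate

Runs generated here are realizations of the neutral model itself, so
passing tests show internal consistency and agreement with the model's
exact small-system solution — not realism of any particular empirical
system. The model omits within-population (individual) dynamics, trait
evolution, spatially varying `K_L`, and vicariant (range-splitting)
speciation; range sizes, ages and tree shapes should be read accordingly.
Equilibrium behaviour reproduced by the package includes: richness
saturating below `K_R` when `mu > 0` and exactly at `K_R` when `mu = 0`
(all ranges 1), right-skewed range-size distributions, turnover near 1 at
equilibrium, and a diversification slowdown that is weaker in
reconstructed than in full trees.

## Problem sizes and numerical choices

The test suite runs scenarios up to `A = 4096` at 20 replicates and checks
state invariants across million-event runs; the acceptance script uses 20
replicates per scenario, single runs for deterministic endpoints
(saturation), and the full parameter values of the study throughout —
replicate counts, not parameters, are what is scaled down. The
effectively-unbounded scenario (`K_L = 1500`, `K_R = 384000`) is provided
as a built-in 50-replicate scenario but is not exercised by the default
suite: populations grow into the hundreds of thousands and, under the
built-in high-rate pair, the run can reach the species cap before `T`, in
which case it is flagged as truncated rather than silently clipped.

Ties and degeneracies: simultaneous events have probability zero in
continuous time; a species extinction shares its timestamp with the event
that removed the last population; `delta_r` returns `NA` whenever any
anchor count is zero; `sackin_normalized` and confidence intervals return
`NA` below the sizes at which they are defined (2 tips, 2 replicates).
Newick output uses 12 significant digits, which round-trips branch lengths
to well below the waiting-time scale of any plausible run.
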