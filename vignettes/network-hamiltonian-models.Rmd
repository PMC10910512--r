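---
title: "Network Hamiltonian models of amyloid fibril self-assembly"
author: "fibrilNHM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network Hamiltonian models of amyloid fibril self-assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilNHM)
```

## The model

A network Hamiltonian model (NHM) is a coarse-grained description of an
aggregating protein system in which all spatial detail is discarded: the
state is an undirected simple graph $g$ on $N$ labeled nodes, one node per
molecule, with an edge wherever two molecules share a noncovalent bond. The
energy of a configuration is a linear function of graph topology,

$$H(g) = \sum_X \phi_X \, t_X(g),$$

where each sufficient statistic $t_X(g)$ counts the subgraphs of type $X$
in $g$ and $\phi_X$ is its energetic coefficient in units of $k_BT$
(negative = formation of that motif is favorable). Configurations follow
the Boltzmann distribution $P(g) \propto \exp(-H(g)/k_BT)$ with a uniform
reference measure, which makes the model an exponential-family random
graph model (ERGM) in the statistical parameterization
$P(g) \propto \exp(\theta^\top t(g))$ with $\theta = -\phi/(k_BT)$. The
package fixes $k_BT = 1$ by default; all shipped coefficient sets are
expressed at that scale.

The supported statistics are `edges`, `twostar`
($\sum_v \binom{\deg v}{2}$), the null-shared-partner counts `nsp1`/`nsp2`
(non-adjacent pairs with exactly 1 or 2 common neighbors), the edgewise
counts `esp0`/`esp1` (edges whose endpoints share exactly 0 or 1
partners), and `cycle3`/`cycle5`/`cycle6`/`cycle7` (simple cycles of that
exact length, counted once each). These are plain counts, not
geometrically weighted variants; shared-partner counts above $k = 2$
(null) and $k = 1$ (edgewise) are not needed by any shipped model and are
not implemented.

### System-size offsets

The edge coefficient absorbs a log-of-size offset so one model transfers
across system sizes: simulation uses
$\theta_e = -(\phi_e + c - \ln N)$ with offset constant $c = 1$ (the other
coordinates are plain sign flips), and a model tuned at size $N_1$ is
moved to $N_2$ by $\phi_e \mapsto \phi_e + \ln N_1 - \ln N_2$
(`rescaleEdgePhi`). The $+1$ constant is implemented exactly as the model
presets require; `phiToTheta(..., edgeOffset = FALSE)` gives the plain
$\theta = -\phi$ conversion, and `offsetConst` makes the constant
configurable. The offset's intuition: the baseline likelihood that two
specific molecules meet falls as the system grows, so the per-edge reward
must shrink with $\ln N$.

## Sampling

`simulateDraw` runs Metropolis–Hastings over graphs. Each proposal is
evaluated through *change statistics* — the difference $\Delta t$ a move
causes, computed from the local neighborhood only, never by recounting the
graph — and accepted with probability
$\min(1, e^{\theta^\top \Delta t})$. Running statistics are maintained
incrementally and equal a full recount of the final graph exactly (an
invariant the test-suite checks).

Two symmetric proposal types are mixed:

* **Dyad toggles** (probability `1 - swapFraction`): a uniformly random
  node pair is toggled. This is the minimal ergodic kernel and the only
  one that changes the edge count.
* **Degree-preserving double-edge swaps** (probability `swapFraction`,
  default 0.5): two uniformly chosen existing edges $u\!-\!v$, $x\!-\!y$
  are replaced by $u\!-\!x$, $v\!-\!y$ (pairing chosen at random;
  proposals that would collapse onto existing edges or shared nodes are
  rejected). Both endpoints states have the same edge count, so the
  selection probabilities cancel and the kernel is symmetric.

The swap kernel exists because the fibril-forming models in this package
combine a strongly positive edge reward with a strong 2-star penalty. With
toggles alone, a chain quenches within a few sweeps into a random
near-regular graph; reorganizing that graph into the ordered fibril state
requires passing through degree-defect intermediates penalized by tens of
log-units per step, so ordering essentially never happens even though the
ordered state is favored by hundreds to thousands of log-units (this can
be verified directly by comparing $\theta^\top t$ of a perfect fibril with
a typical toggle-only draw). Swaps cancel the degree terms and let local
order anneal at fixed density, the way lattice models are equilibrated at
fixed particle number. Both kernels target the identical distribution;
the dyad-independent closed forms (edge density $e^{\theta_e}/(1 +
e^{\theta_e})$ for an edges-only model) hold under either and are tested
under both.

Defaults: the chain starts from the empty graph (a fully disaggregated
monomer system, which makes nucleation-and-growth observable), runs
$50\binom{N}{2}$ proposals per draw (several expected visits per dyad),
and aborts with a typed degeneracy error if the edge count exceeds
$8N$ — runaway densification is the classic ERGM failure mode, and the
parameter search must survive visits to such regions rather than crash.
Ensembles derive per-replicate seeds deterministically from one master
seed, so results are independent of evaluation order and bitwise
reproducible.

## The fibril-fraction assay

Five periodic fibril topologies ship as templates: `1-ribbon` (a single
bonded strand), `2-ribbon` (a two-strand ladder), `1,2 2-ribbon` (the
ladder plus one diagonal bond family — the steric-zipper-like cross
pattern, interior degree 4), `double 1,2 2-ribbon` (two such ribbons
joined by rungs), and `3-prism` (three strands closed into triangles). A
template is *data*, not code: `strands` plus a set of edge rules
$((a, b), \Delta i)$ bonding node $(a, i)$ to $(b, i + \Delta i)$, with
axial offsets restricted to 0 and 1. Users can override any rule set, and
`buildFibril` realizes a template as a linear or cyclic (wrap-around)
graph.

`fibrilNodes` counts a node as fibrillar only under strict conditions: it
must occupy an interior (non-terminal) position of an embedded segment
spanning at least `minUnits` (default 3) repeat units in which every
template edge is present, and its degree must equal the template's
interior degree for its strand, so it carries no bonds outside the
matched pattern. Fibril ends therefore never count, and a single
off-pattern chord disqualifies exactly the nodes it touches. This
deliberate undercounting rewards long, defect-free fibrils — the right
bias for a fitness function that should favor models producing extended
ordered structure. Overlapping matched segments contribute the union of
their interior nodes, and the fraction is invariant under node
relabeling.

Because the topologies are defined here from their names, interior
degrees, and the steric-zipper description, the rule sets for the
`1,2 2-ribbon` and especially the `double 1,2 2-ribbon` are
reconstructions. Ranking candidate structures by model probability shows
the shipped `1,2 2-ribbon` template is the most probable periodic state
of its own optimized model, supporting that reconstruction; the optimized
`double 1,2 2-ribbon` coefficients, by contrast, prefer denser weakly
ordered states over every plausible double-ribbon rule set tried, so
scores for that topology are not comparable across assay implementations
with different rule sets.

## The genetic algorithm

`runEvolution` searches coefficient space for maximal mean fibril
fraction. The moving parts, with their typical values:

* **Fitness**: `reps` (16) independent equilibrium draws at `nNodes`,
  each scored by the assay; the mean is the fitness. Low `reps` favors
  lucky multimodal parameters; high `reps` favors consistent performers.
  Degenerate draws score 0 rather than aborting the run.
* **Breeding**: every survivor pair is connected by a line in coefficient
  space; `floor(minLineDensity * d)` (density 1.2) *linear children* sit
  at evenly spaced interior points (endpoints excluded — parents are
  copied separately), and each gets `mutantsPerChild` *mutant* copies
  with i.i.d. Gaussian noise of variance `noiseVarInit` (1.0) per free
  dimension. Pairs closer than one child spacing are deemed too related
  to breed (inbreeding avoidance); litters above `childMax` (100) are
  randomly thinned. This line-breeding scheme explores the convex hull of
  the current survivors, where better parameters tend to lie.
* **Selection**: rank by mean fitness (ties broken by lower id); the top
  `topFraction` (0.25) survive, randomly thinned to `maxSurvivors` (20).
  Generation 0 is treated as the user's chosen breeding population: it is
  ranked and capped but never thinned by `topFraction`.
* **Generation rejection**: if no child strictly outperforms the best
  parent, the entire generation is removed from the gene pool and the
  parents rebreed, with the mutant variance doubled (`smartVar`) and one
  extra mutant per linear child (`smartPts`). Retries are capped
  (`maxRetries`, default 5) to bound compute; a run that exhausts the cap
  reports a stall rather than looping forever. Both escalations persist
  into later generations once triggered.
* **Immortality**: every accepted generation contains copies of all its
  parents, so a consistently top parameter persists indefinitely and the
  best-of-run trajectory is nondecreasing by construction.
* **Fixed edges**: with `fixEdge` on, the edge coordinate is excluded
  from sampling, breeding, and mutation. `fixEdgeValue` (100) is a
  $\theta$-form value; the pinned $\phi$ coordinate is
  $-\mathrm{fixEdgeValue} - 1 + \ln N$, which converts back to exactly
  $\theta_e = \mathrm{fixEdgeValue}$.
* **Reproducibility**: per-individual simulation seeds derive from the
  master seed and the individual's id, so fitness values do not depend on
  evaluation order; breeding and selection randomness is seeded per
  generation and attempt. Two runs with one master seed are identical.

Generation-0 clouds come from `seedSphere`: points uniform in a ball over
the free dimensions. For the 2-ribbon-from-random demonstration (four
low-yield starting parameterizations with $\theta_e$ fixed at 100), the
ball is centered at the origin with radius 40 — wide enough to contain
the known productive region of the $(2\text{-star}, \mathrm{NSP1},
\mathrm{NSP2})$ space with substantial margin, so the screen finds mostly
dead parameters and a few weak producers, which is the intended starting
condition.

## Numerical choices and problem sizes

Seeds are kept below $2^{31}$ throughout (R integers are 32-bit); derived
seed streams use fixed multiplicative constants with exact double
arithmetic. Cycle counting canonicalizes each simple cycle by its minimum
node and counts each once; change statistics for cycles count simple
paths between the toggled endpoints with breadth-first pruning, which
keeps bounded-degree sparse graphs cheap. Selection tie-breaks and
child-thinning are deterministic given the seed. Empty graphs, empty
populations, single-individual generations, and self-loop dyads are
rejected or handled explicitly.

The test-suite exercises the full pipeline at sizes a laptop handles in
minutes: statistics and change statistics are verified against
brute-force enumeration and an independent subgraph-isomorphism counter
on graphs of up to 8 nodes ($\geq$ 1000 randomized toggles), sampler
closed forms on 10–20 nodes, the assay on templates of up to ~50 nodes,
preset equilibrium behavior at the published 256-node size with tens of
draws, and the evolutionary search at 48 nodes with reduced population
caps (survivors 5, `childMax` 8, `reps` 4). The synthetic-landscape
recovery test uses mutant noise 0.04 because its target lives on a unit
scale, unlike the $\sim$40-unit fibril coefficient space.

## What the fixtures do and do not show

The built-in fixtures (perfect and damaged fibrils, the four-node worked
example, seeded parameter clouds) are idealized: real aggregation data
have polymorph mixtures, partial order, and finite-size boundary effects
that a periodic template with strict matching deliberately scores
against. Passing tests show the machinery is exact on its own
definitions — they do not show that any particular coefficient set
describes a particular protein, which requires the system-specific
parameterization workflow the GA provides.

## Known limitations

* Equilibration depth is a real experimental condition: with the mixed
  kernel the 2-ribbon model reaches complete ladders (fraction 1.0) at
  256 nodes, while the 1,2 2-ribbon and 3-prism models order only
  partially at feasible burn-in — their perfect templates remain the
  most probable states, but within-density annealing of the remaining
  defects is slow. Reported fractions are therefore kernel- and
  schedule-dependent for those models.
* The `double 1,2 2-ribbon` template is a reconstruction that its own
  optimized coefficients do not prefer; absolute fractions for that
  topology are assay-definition-dependent.
* The GA's terminal resolution is set by the inbreeding-avoidance
  spacing ($\approx 1/\mathrm{minLineDensity}$) plus mutant noise;
  refining an optimum much below the noise scale requires re-running
  with smaller `noiseVarInit`.
* Directed graphs, weighted edges, node covariates, and
  geometrically-weighted ERGM terms are out of scope; temperature
  scheduling (annealing) and likelihood-based fitting are deliberately
  not provided — the GA is the only fitting procedure.
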