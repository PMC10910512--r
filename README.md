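# fibrilNHM

Simulation and automated parameterization of **network Hamiltonian models
(NHMs)** of amyloid fibril self-assembly.

Amyloid fibrils — the ordered protein aggregates behind Alzheimer's,
Parkinson's, and the functional amyloids of normal biology — assemble from
thousands of monomers on timescales far beyond atomistic simulation. An NHM
coarse-grains the problem to pure topology: the system is an undirected
simple graph on *N* labeled nodes (one per molecule, an edge per noncovalent
bond), with energy

H(g) = Σ_X φ_X · t_X(g)

where each sufficient statistic t_X(g) counts subgraphs of type X (edges,
2-stars, shared-partner motifs, cycles) and φ_X is its energetic coefficient
in units of k_B·T. Graphs follow P(g) ∝ exp(−H(g)/k_B·T) — an
exponential-family random graph model (ERGM) with θ = −φ, sampled here by
Metropolis–Hastings with incremental change statistics. The package is for
structural/computational biophysicists who want to simulate fibril
formation, score graphs against the five experimentally observed fibril
topologies (*1-ribbon*, *2-ribbon*, *1,2 2-ribbon* / steric zipper,
*double 1,2 2-ribbon*, *3-prism*), and discover new coefficient sets with
the built-in genetic algorithm, whose fitness is the **fibril fraction**:
the share of nodes inside regions of perfect periodic fibril structure
(interior nodes only — ends and defects deliberately do not count).

## Worked example

Count statistics on a four-node demonstration graph (a triangle A–C–D plus
pendant edge A–B), then draw an equilibrium 256-node sample of the shipped
1-ribbon model and assay it:

```r
library(fibrilNHM)

g <- makeFixture("four-node-example")
computeStats(g, c("edges", "twostar", "nsp1", "nsp2", "esp0", "esp1", "cycle3"))
#>   edges twostar    nsp1    nsp2    esp0    esp1  cycle3
#>       4       5       2       0       1       3       1
```

Two non-adjacent pairs (B,C and B,D) share exactly one partner (`nsp1 = 2`),
one edge joins endpoints with no shared partner (`esp0 = 1`, the pendant
bond), and the triangle is the single 3-cycle.

```r
m <- modelPreset("1-ribbon")      # phi: edges -107.22, twostar 37.33, nsp1 1.35
phiToTheta(m, 256)                # theta_e = -(phi_e + 1 - ln N)
#>    edges  twostar     nsp1
#> 111.7652 -37.3300  -1.3500

d <- simulateDraw(m, 256, samplerConfig(seed = 5))
fibrilFraction(drawGraph(d), "1-ribbon")
#> [1] 1
```

The strongly positive edge reward and strong 2-star penalty drive every
node to exactly two bonds; the equilibrated draw is a set of closed
1-ribbon loops covering all 256 nodes, hence fibril fraction 1.0.

To evolve coefficients instead of using a preset, see `?runEvolution`
(generation-0 clouds from `seedSphere`, all-pairs line breeding, strict
generation acceptance, parent immortality) and the package vignette for
the algorithm's hyperparameters and design rationale. A command-line
interface (`inst/scripts/nhm.R`) exposes `stats`, `assay`, `simulate`, and
`evolve` subcommands over edge-list/GraphML files and YAML run
configurations.

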