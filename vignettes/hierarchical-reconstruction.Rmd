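---
title: "Hierarchical reconstruction of 3D chromosome models from Hi-C"
author: "hichier package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical reconstruction of 3D chromosome models from Hi-C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hichier)
```

# The problem

Hi-C measures, genome-wide, how often pairs of genomic loci touch in the
nucleus. Binned at a fixed resolution, the counts form a symmetric
contact matrix whose entries (interaction frequencies, IFs) decay with
spatial distance. Reconstructing a 3D polymer model that realizes those
contacts is a distance-geometry problem, and at high resolution (5 kb
bins, tens of thousands of beads per chromosome) it becomes both huge
and under-determined: contacts per bead thin out as bins shrink, and
many topologically different conformations can satisfy the same sparse
data.

`hichier` attacks this with a hierarchy that mirrors how chromosomes are
organized. Topologically associating domains (TADs) are contact-dense
structural units, so each TAD sub-matrix supports an accurate
high-resolution model on its own. A whole-chromosome model built at
domain resolution (one bead per TAD) is stable because aggregated
contacts are abundant. The pipeline therefore:

1. partitions the chromosome into domains (supplied BED calls, or the
   bundled insulation-score caller);
2. aggregates contacts between domains, ICE-balances the small matrix,
   and builds a low-resolution scaffold (one bead per domain);
3. extracts each domain's intra-domain sub-matrix;
4. KR-balances each sub-matrix and builds a high-resolution model per
   domain, with a consensus conversion exponent;
5. estimates the scale relating domain models to the scaffold and
   rescales the scaffold;
6. substitutes each domain model at its scaffold bead (centroid on
   bead, orientation unchanged);
7. refines the assembled model against *all* contacts.

# The model

## From frequencies to distances

The expected spatial distance of a contacting pair is

$$ d_{ij} = \mathrm{IF}_{ij}^{-\alpha}, $$

with a conversion exponent $\alpha$ selected per matrix by grid search
over $[0.1, 3.0]$ in steps of $0.1$. Each candidate is scored by the
Spearman correlation between realized model distances and the expected
distances. A subtlety: the *rank target* is identical for every
$\alpha$ (all candidates are monotone transforms of one another), so
the score can discriminate only through embedding failure — at the
data-generating exponent the expected distances are exactly realizable
in 3D, away from it they are geometrically frustrated. This makes
comparable convergence quality across candidates essential: every
candidate model starts from a classical-MDS (spectral) embedding of its
expected-distance matrix, completed by graph shortest paths where
contacts are missing, and is polished by gradient ascent with a reduced
(one fifth) iteration budget. Domain models are then *rebuilt* at the
median (consensus) exponent of all domains so that distance units agree
across domains — a requirement of the scale estimator below.

## The Lorentzian objective

Bead coordinates maximize

$$ F(X) \;=\; \sum_{(i,j)} w_{ij}\,
   \frac{\gamma^2}{\gamma^2 + \left(\lVert x_i - x_j\rVert -
   \delta_{ij}\right)^2}, $$

with $\delta_{ij} = \mathrm{IF}_{ij}^{-\alpha}$ and weights
$w_{ij} = \mathrm{IF}_{ij} / \max \mathrm{IF}$. The Cauchy (Lorentzian)
kernel gives every restraint a bounded influence: a contact that cannot
be satisfied — noise, or a population-average artifact — flattens out
of the gradient instead of dragging the model, while the IF-derived
weights prioritize the reliable, high-frequency contacts. The kernel
width is $\gamma = 0.3 \cdot \mathrm{median}(\delta)$ by default
(`gammaFrac`): wide enough that neighboring restraints interact
smoothly, narrow enough to resolve structure at the scale of typical
expected distances. Consecutive beads sharing no contact receive a
chain-adjacency restraint (weight `adjacencyWeight = 0.5`, distance =
median expected distance of observed consecutive pairs) so the polymer
stays connected.

Optimization is adaptive-step gradient ascent under graduated
non-convexity: the width is annealed from $10\gamma$ down to $\gamma$
over four geometric stages (`annealStages`, `annealStart`), each stage
a strictly monotone ascent seeded from the previous one. The wide
kernel early on smooths away local optima — without it, random
initializations routinely stall far from a perfect embedding even on
noise-free data; with it, complete noise-free instances are recovered
to a fraction of a percent. When an explicit initialization is given
and annealing would end below that initialization's objective at the
target width, a direct single-stage ascent from the initialization is
used instead, so results never fall below their starting point (the
property refinement relies on). Proposals scale the gradient so the
fastest bead moves `step`; accepted proposals grow the step by 1.1,
rejected ones shrink it by 0.5, and a stage stops after 30 consecutive
proposals without a relative improvement of `tol = 1e-6`.

## Balancing

Per-domain matrices are balanced with Knight–Ruiz (the inner–outer
Newton iteration on the symmetric matrix; unit target row sums), the
domain-level matrix with ICE (iterative row-bias correction). ICE here
stops when the maximum relative deviation of row sums is below `tol` —
a slightly stronger condition than a coefficient-of-variation test, so
that "row sums equal within tol" holds literally — and rescales the
result to preserve the input's mean off-diagonal IF, keeping domain
sums interpretable. Bins with no or almost no off-diagonal partners
(fewer than `minNonzeroFrac = 0.02` of bins) are excluded from
balancing and from the model; indices are preserved rather than
re-packed, and such bins are simply absent from the output structure.
Because excluded bins are representationally identical to bins that
never had contacts, the balancers silently skip entry-less bins instead
of raising an error. A reducible (disconnected) matrix is balanced one
connected component at a time, with a warning.

## The scale between resolutions

Domain models (KR units) and the scaffold (ICE units) have unrelated
scales. For each pair of genomically adjacent domains $x, y$ — adjacent
pairs are used because their inter-domain contacts are most enriched —
the center-to-center distance is estimated as

$$ d_{xy} = \min_{i \in x,\, j \in y}
   \left( d_{ij} + d_{xi} + d_{yj} \right), $$

where $d_{ij}$ is the expected distance of an inter-domain contact and
$d_{xi}, d_{yj}$ are model distances from each domain's centroid to the
contacting bead. Every candidate sum upper-bounds the true center
distance (triangle inequality), and with many contacts the minimum is a
tight estimate — on exact synthetic geometry it lands within a few
percent. Dividing by the corresponding scaffold bead distance gives up
to $n-1$ ratios; their median rescales the scaffold. In the pipeline
the inter-domain IFs entering $d_{ij}$ come from a KR-balanced
sub-matrix spanning the two domains, approximating the units in which
the domain models were built; `balance = "none"` exists for validation
against ground-truth models expressed in raw units. Pairs with no
inter-domain contact are skipped; if no pair has one, the scale is an
error rather than a guess.

## Refinement

The assembled model is re-optimized against the complete restraint set
at the consensus exponent. Whole-map restraints are in raw-IF units
while the assembled model is in KR-derived units, and the Lorentzian's
flat tails would stall an ascent started at a badly mis-scaled
configuration; refinement therefore first line-searches a single global
scale factor for the initial model (candidates bracket the
median-distance ratio; 1 is always a candidate and wins ties) and then
ascends. Intra-domain geometry, already near-optimal, is mostly
preserved; the gain concentrates in inter-domain restraints — measured
explicitly by `domainRestraintObjective()`, and asserted in the test
suite on every seeded synthetic run.

# The synthetic-data generator

`generateStructure()` builds domain centers by a self-avoiding random
walk (step `backboneStep = 3`, rejection within half a step, 1000
retries) and fills each domain with a reflected random walk inside a
sphere of radius `domainRadius = 1` — compact globules on a string,
reproducing the two properties the method relies on: intra-domain
contact enrichment and a chromosome-scale backbone. `simulateContacts()`
inverts the conversion law exactly, $\mathrm{IF} = \mathrm{depth} \cdot
d^{-1/\alpha_{\mathrm{true}}}$, keeps pairs below the 95th distance
percentile (Hi-C sparsity), and optionally Poisson-samples each count
(dropping zeros). Defaults — 10 domains of 30 bins at 5 kb,
$\alpha_{\mathrm{true}} = 1$, depth 100, Poisson noise — are the study
conditions used by the test suite and the acceptance script; they give
IFs of order 100 for close pairs and order 10 between distant domains,
a realistic deep-coverage regime at this problem size.

What the simulator does *not* emulate: genomic-distance–dependent decay
beyond what geometry induces, loop extrusion or CTCF-anchored loops,
A/B-compartment plaid structure, unmappable regions, or replicate
variability. Passing the recovery tests therefore demonstrates
correctness of the algorithmic chain under the model's own assumptions
— not that real Hi-C data satisfies those assumptions.

# Numerical choices and degenerate inputs

* Grid-search ties go to the smaller exponent; a constant-IF matrix is
  rejected as degenerate (every exponent fits equally), except in
  scaffold building where a single-entry domain matrix falls back to
  $\alpha = 1$.
* A single-bin domain is modeled as one bead at the origin; a domain
  with no usable intra-domain contacts becomes a straight segment with
  unit spacing (warning).
* Coincident beads contribute a zero direction to the gradient (a
  subgradient choice); coincident bead pairs are skipped by the
  simulator with a warning.
* Mirrored duplicate entries in input files are merged; conflicting
  values (relative difference above 1e-9) are an error, never silently
  averaged.
* Insulation boundaries: score squares truncated at chromosome ends are
  undefined; flat minima report their leftmost bin; prominence is the
  smaller rise to the nearest higher flanking local maxima.
* All stochastic steps (initialization, simulator, Poisson sampling,
  optional domain rotations) run under explicit seeds derived from the
  configuration, so every pipeline output is bit-reproducible.

# Design choices that were genuinely open

* **Orientation at substitution** is the identity; refinement is
  responsible for orienting domains, and identity keeps the pipeline
  deterministic. Seeded random rotations are available
  (`rotateDomains`) for robustness experiments.
* **Aggregation uses raw IF sums**, then ICE: domain visibility scales
  with domain length, which is exactly the bias ICE removes; averaging
  first would hide it.
* **Domain models are rebuilt at the consensus exponent** rather than
  kept at their per-domain exponents: the scale estimator compares
  distances across domains and needs a common unit.
* **Un-domained gaps become domains of their own**, so every bin is
  modeled exactly once.
* **Grid-search scoring uses Spearman correlation**, the same metric
  used for model evaluation, with embedding feasibility providing the
  discrimination (see above).

# Problem sizes

The test suite and acceptance script run the full pipeline on a
300-bead chromosome (10 domains x 30 bins) with Poisson noise, exponent
recovery on 60-bead noise-free maps, balancing checks on 50 x 50
matrices, and exact-embedding recovery on 20-bead complete instances —
sizes at which every stage's behavior is measurable in seconds while
leaving no algorithmic path unexercised. The same code runs unchanged
on real intra-chromosomal dumps at 5 kb; runtime is dominated by the
refinement stage, which is linear in the number of contacts per
iteration.

# Known limitations

* Chirality: all similarity measures are mirror-blind; Hi-C itself
  cannot determine handedness.
* Single consensus structure: cell-to-cell variability is averaged, not
  deconvolved; no ensemble output.
* The insulation caller is a pragmatic substitute for corner-score
  domain callers; externally called domains (BED) are the recommended
  input when available.
* Whole-genome (trans-contact) assembly and `.hic`/`.cool` binary
  readers are out of scope; inputs are plain-text dumps.
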