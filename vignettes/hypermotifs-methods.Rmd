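---
title: "Methods: motif assemblies, their enrichment, and their dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif assemblies, their enrichment, and their dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypermotifs)
```

Network motifs — recurring small subgraph patterns such as the feedforward
loop (FFL), mutual feedback circuits and three-node loops — are the
building blocks of directed networks. This package studies the next level of
organization: how two motifs are *joined*. Two motifs can be joined in two
ways: a **combination**, where they share at least one node, and an
**interaction**, where they are linked by at least one cross-edge. This
vignette documents the models, the statistical procedure, the numerical
choices and the known limitations; the README shows a worked example.

## Counting combinations and interactions

Two motifs with $n_A$ and $n_B$ nodes can share $N_v$ nodes with
$1 \le N_v < \min(n_A, n_B)$: sharing $\min(n_A, n_B)$ nodes would absorb
the smaller motif entirely. The identity of the shared nodes — which *roles*
of each motif are merged — defines a core combination topology. Roles are
the automorphism orbits of the motif digraph: positions mapped onto each
other by some symmetry of the motif are interchangeable, so the FFL has
three roles (input, intermediate, output) while the directed three-node
loop and the mutual dyad each have one.

`enumerate_combinations()` scans every assignment of shared role positions
at every admissible $N_v$, builds the merged digraph, and deduplicates the
merged graphs up to isomorphism, which also identifies patterns related by
exchanging the two motifs when they belong to the same class. A design
choice arises when the merge lets one motif's edges run *inside* the other
motif's node set: we require by default (`strict = TRUE`) that each motif
remain an **induced** occurrence on its designated nodes, which is our
operational reading of "the autonomy of each motif's topology is
maintained". Under this convention two FFLs can be joined in exactly 12
distinct ways (6 with one shared node, 6 with two), two mutual dyads in 1,
and a mutual dyad with an FFL in 3; the permissive convention
(`strict = FALSE`, each motif only required as a subgraph on its own edges)
admits 18 FFL–FFL cores. Both are available; the count of merges excluded
by the strict rule is attached to the result.

For interactions, every cross-motif node pair can carry up to two directed
edges, so there are at most $2 n_A n_B$ linking edges and
$2^{2 n_A n_B}$ labeled cross-edge configurations ($2^{n_A n_B}$ in the
undirected case). These formula counts include the empty configuration and
do not collapse isomorphic duplicates — `enumerate_interactions()` and
`enumerate_extensions()` perform deduplicated enumeration on concrete
motifs where that is wanted.

## The census and the canonical form

All statistics are built on an exact census of weakly-connected three-node
induced subgraphs. Each subgraph is classified by a canonical key: the
minimum, over all node permutations, of the off-diagonal adjacency bit
string (bits ordered pairwise: $(1{\to}2), (2{\to}1), (1{\to}3), \dots$).
At $k \le 4$ nodes the $k!$ permutations are enumerated outright, so the
canonicalization is exact by construction; the 64 labeled three-node
digraphs fall into 16 classes, 13 of them connected. Occurrences are
position-normalized: the nodes of each instance are listed in canonical
position order, with ties among automorphic orderings broken by the
lexicographically smallest node tuple, so every occurrence is reported
exactly once. Self-loops are ignored by the census and held fixed by the
randomizers (a self-loop is a one-node pattern, not part of the three-node
census).

## Detecting enriched combinations

Given a network, the pipeline in `detect_hypermotifs()`:

1. **Designates motif classes.** By default, three-node classes whose count
   exceeds the degree-preserving switching null by more than
   `z_threshold = 2` standard deviations; the cutoff is configurable and an
   explicit class list can be supplied instead.
2. **Assigns roles.** Every node participating in a designated motif is
   assigned to the role groups (class × orbit) it occupies, with
   multiplicity across instances.
3. **Scores overlaps.** For every unordered pair of distinct roles, the
   Jaccard index $J(n_i, n_j) = |n_i \cap n_j| / |n_i \cup n_j|$ of the
   deduplicated role node sets; for every role by itself (the diagonal),
   the fraction of nodes that occupy that role more than once.
4. **Builds the null.** An ensemble (default 100) of randomized networks
   that preserve the node count, edge count, every node's in- and
   out-degree, the mutual-dyad count and the *exact* count of every
   connected three-node subgraph class. Preserving the census is what makes
   the statistic specific to how motifs are *arranged* rather than how many
   there are.
5. **Calls enrichment.** Each statistic gets a Z-score against its null
   distribution, a one-sided normal p-value in the direction of the Z-score
   (matching the separation of over- and underrepresentation by the sign of
   Z), Benjamini–Hochberg adjustment across all non-degenerate records
   jointly (diagonals included), and a call of "over" ($Z > 0$) or "under"
   ($Z < 0$) when $q < \alpha$ (default 0.05).

Records whose null standard deviation is zero are flagged degenerate,
reported with $Z = 0$, excluded from the BH family and never called —
reporting an infinite Z-score would be meaningless when the constraints pin
the statistic.

### The census-preserving sampler

Exact census preservation is achieved by degree-preserving edge switching
(five accepted double-edge swaps per edge) to scramble the network,
followed by simulated annealing on the L1 distance between the census
count vectors (plus the mutual-dyad term): double-edge swap proposals are
accepted when they do not increase the distance, and with Metropolis
probability $e^{-\Delta E / T}$ under a geometric cooling schedule
otherwise, terminating at distance zero. Distance-zero states exist because
the walk is reversible and the original network is one of them. The
proposal evaluation is incremental — only triples containing a changed node
pair are re-classified, found through the skeleton neighborhoods of the
four affected nodes — which keeps a sample of a few-hundred-node network in
the seconds range. Samples that fail to reach distance zero within the
iteration budget are retried from a fresh sub-seed and an error with
diagnostics is raised if retries are exhausted. Sample $i$ of an ensemble
is driven by `seed + i`, making ensembles bit-reproducible.

We preserve the census *exactly* (strictest reading of "same frequency of
all subgraphs"), and only up to three-node subgraphs: a null preserving
four-node censuses is out of scope. Note that with degrees, the
mutual-dyad count and the connected triad census fixed, the counts of the
disconnected triad types are fixed as well, so the full 16-class triad
census is preserved.

## Synthetic validation networks

Because enrichment can only be validated against a known ground truth, the
synthetic module generates study networks: a uniform random simple digraph
background (`generate_background()`) plus planted pattern copies
(`plant_patterns()`) with a manifest of the planted motif instances in
canonical order. The standard validation setting,
`synthetic_cascade_network()`, plants copies of the output-to-input FFL
cascade — the layered arrangement in which the output of one FFL is the
input of the next — on fresh nodes. Defaults are a 150-node, 300-edge
background (mean degree 4, a sparsity comparable to transcription
networks) with 30 planted cascades, chosen to give the detector clear
headroom while background FFLs remain rare (about $n^3 p^3 \approx 8$
expected). Planted copies use fresh nodes by default so the ground truth is
unambiguous; a `reuse = "background"` policy wires copies onto existing
nodes to stress the pipeline. What passing these tests shows is that the
pipeline recovers arrangements *of this planted kind* at this size and
density; real networks add degree heterogeneity, overlapping motifs and
noise that the uniform background does not emulate, so calls on real data
still require the usual scrutiny.

## Hill-function circuit models

Circuit dynamics use the standard Hill formalism: every dynamical node
$X$ obeys
$$\dot X = \beta_X \, G_X(\text{regulators}) - \alpha_X X,$$
with an activating regulator $Y$ contributing $Y^n/(k^n + Y^n)$, a
repressing one $k^n/(k^n + Y^n)$, and multi-input nodes combining
contributions with AND logic (product) by default or OR logic
($1 - \prod(1 - h_i)$) where a fixture documents it. A node may instead be
an external input held at a step level. Parameters default to
$\beta = \alpha = 1$, $n = 2$, $k = 0.5$; every fixture that needs a
specific regime overrides them, and the override is part of the fixture
definition (readable via `write_circuit()`).

Fixture parameter rationale (all verifiable with `find_fixed_points()` and
`simulate_circuit()`):

* **SL** (positive autoregulation), $k = 0.4$: at the default $k = 0.5$,
  $n = 2$ the system sits exactly at the saddle-node bifurcation
  ($x^2 - x + k^2$ has a double root), so $k$ is pulled below 0.5 to give
  the clean bistable pair $x = 0.2$ (threshold) and $x = 0.8$ (ON).
* **TMFL / LMFL** (mutual repression / activation), $k = 0.3$: the same
  marginality argument applies at $k = 0.5$; at 0.3 the toggle has two
  asymmetric stable states and a symmetric saddle, the Lock-ON has stable
  OFF–OFF and ON–ON states.
* **OMFL** (activator–repressor pair), $k = 0.3$, $n = 4$: the interior
  fixed point is always a spiral (eigenvalues $-\alpha \pm i\sqrt{ab}$),
  and the steeper slope makes several damped-oscillation peaks visible
  before decay.
* **Self-loop variants** gate the self term with the partner input (AND).
  The toggle gains a stable OFF–OFF state; the Lock-ON gains nothing (it
  is already bistable); the oscillator with self-loops ($k_{self} = 0.15$,
  chosen so the interior spiral stays clearly stable) gains exactly two
  stable states — OFF–OFF and activator-only; a repressor-only state is
  impossible because the repressor cannot rise without the activator.
* **FFLs**: coherent and incoherent type-1 with a step input;
  $k_{XZ} = 0.05$ makes the output responsive to low inputs and
  $k_{YZ} = 0.15$ makes the repression arm strong, which produces the
  classic incoherent pulse. With a self-activating intermediate
  ($k_{YY} = 0.3$), a high input ($X = 0.5$) sustains the intermediate and
  the output pulses, while a low input ($X = 0.1$) lets the intermediate
  collapse and the output rises, delayed, to a high steady state — the
  initial levels $Y_0 = 0.185$, $Z_0 = 0.19$ used in the examples sit
  between the two basins.
* **Coupled assemblies**: two double-mutual-feedback circuits sharing a
  repressing edge oscillate in phase when the repressed side turns over
  slowly ($\alpha = 0.3$ on all nodes but the repressor, mutual
  $k = 0.15$, $n = 4$); two three-node loops sharing an edge (one
  repression, $\beta = 1.5$, $n = 4$) oscillate with the two distinctive
  nodes in anti-phase; a coherent FFL activating an incoherent FFL that
  represses it back (OR gates, $k = 0.3$, $n = 2$) forms a long delayed
  negative loop that oscillates although any feedforward circuit alone has
  a triangular Jacobian with real negative eigenvalues and cannot.

## Numerical choices

* Integration: `deSolve::ode` (lsoda), relative tolerance $10^{-8}$;
  solver undershoots below zero are clipped (with a warning past
  $-10^{-6}$).
* Fixed points: multi-start damped Newton on a per-dimension grid scaled
  by $\beta/\alpha$; residual tolerance $10^{-9}$; deduplication at
  $10^{-6}$ in state space; classification from numerical Jacobian
  eigenvalues with tolerance $10^{-6}$ (stable node / spiral / saddle /
  unstable; "marginal" when eigenvalues straddle the tolerance).
* Trajectory classification: the first 30% of a trajectory is treated as
  transient; a pulse is a single interior maximum with a final level below
  half the peak; oscillations need repeated peaks (amplitude filter 2% of
  the signal range), sustained when the last peak-to-trough amplitude is
  at least 0.9 of the first post-transient one.
* Synchronization: period from peak spacing, lag from the cross-correlation
  peak; relative lag below 0.1 of the period is in-phase, within 0.1 of a
  half period anti-phase.
* Downsampling: the neighborhood walk uses the union of in- and
  out-neighbors (the sampler exists to preserve connectivity, which the
  undirected neighborhood serves best), continues from the previous node
  with probability 0.85 and otherwise jumps to the anchor's neighborhood;
  the one-third checkpoints use integer floors, and re-drawn anchors are
  used for subsequent jumps without being appended to the walk. The output
  is the induced subgraph on the unique walked nodes.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, as the
package's own choice of study conditions: validation networks of 150–300
background nodes with 10–30 planted patterns, null ensembles of 100 for
detection calls and 4–5 where only the preservation contract is asserted,
and 100-point parameter samples for the no-oscillation property of
feedforward circuits.

## Known limitations

* The census-preserving null is only available for three-node censuses;
  larger motifs would need a different randomization strategy.
* Enrichment covers combinations (shared nodes) only; interaction
  enrichment is not defined by the detection procedure — interactions are
  handled combinatorially and dynamically.
* Combination enumeration is limited to motifs of at most four nodes.
* The ODE layer is deterministic; noise-driven phenomena (e.g. noise
  sustaining otherwise damped oscillations) are out of scope.
* Fixture parameters realize each circuit's characteristic qualitative
  regime; they are not claimed to reproduce any particular published
  trajectory point-for-point.
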