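---
title: "Sigma-k distances and the double distance: models and algorithms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sigma-k distances and the double distance: models and algorithms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The genome model

A genome is a multiset of chromosomes; a chromosome is an ordered sequence
of oriented genes and is either linear (written `[1 -3 2]`) or circular
(written `(4)`).  Genes belong to families; a *singular* genome carries one
gene per family, a *duplicated* genome two.  Each gene `X` has two
extremities, head `Xh` and tail `Xt`.  Neighboring extremities of
consecutive genes form *adjacencies*; the extremities at the two ends of a
linear chromosome are *telomeres*.  A single-gene circular chromosome
`(X)` exceptionally has the adjacency `Xh Xt` within one gene.
Chromosomes are compared up to reverse-complement and, when circular,
rotation; `genome_equal()` and the canonical serialization implement that
normal form by taking the lexicographically smallest representative.

## Breakpoint graph and the sigma-k family

For a *canonical pair* — two singular genomes over the same `n*` families —
the breakpoint graph has one vertex per extremity and one edge per
adjacency of each genome.  Every vertex has at most one edge per genome, so
components are alternating even cycles and paths; an isolated vertex that
is a telomere in both genomes is a 0-path.  Writing `ci` and `pj` for the
numbers of cycles with `i` edges and paths with `j` edges, the family of
scores

    sigma_k = c2 + c4 + ... + ck + (p0 + p2 + ... + p(k-2)) / 2

interpolates between the breakpoint distance `d_2 = n* - sigma_2` and the
DCJ (double-cut-and-join) rearrangement distance `d_inf = n* - sigma_inf`;
the distance is non-increasing in `k`.  Scores live in half-integers, which
doubles represent exactly; the command line prints them as exact decimals
(`2.5`, never floating noise).

```r
library(sigmak)
s1 <- parse_genome("(1 -3 2) [4]")[[1]]
s2 <- parse_genome("(1 2) [3 -4]")[[1]]
sigma_distance(s1, s2, 2)     # 2.5, the breakpoint distance
sigma_distance(s1, s2, Inf)   # 2,   the DCJ distance
```

## The double distance and the ambiguous breakpoint graph

Comparing a singular genome `S` with a duplicated genome `D` requires
doubling `S` first: every adjacency and telomere is duplicated.  When `S`
has `r` circular chromosomes the doubling is realized by `2^r` distinct
doubled genomes, all with the same adjacency and telomere content.  The
sigma-k *double distance* is the minimum sigma-k distance between `D`
(singularized by tagging one copy of each family `a` and the other `b`)
and any singularized doubling of `S`; the result does not depend on the
singularization, so the package picks a deterministic one.

The solution space is encoded in the *ambiguous breakpoint graph*: four
vertices per family (`Xah`, `Xbh`, `Xat`, `Xbt`), one fixed D-edge per
adjacency of the singularized `D`, and, for each adjacency of `S`, a
*square* of four candidate S-edges in two paralogous pairs (parallel and
crossed).  A *solution* keeps one pair per square; its k-score is sigma-k
of the induced breakpoint graph, and the double distance is `2 n*` minus
the maximal k-score.  `oracle_best()` realizes the definition directly by
exhausting all `2^a*` resolutions; it is exponential and capped (default
20 free squares) but provides the independent reference against which the
polynomial solvers are tested.  The DCJ double distance (`k = Inf`) is
NP-hard and exposed only through this oracle.

## What is always optimal

Two reductions are applied first, for every `k`:

* **Common adjacencies and telomeres are conserved.**  Every 0-path and
  every 2-cycle of the ambiguous graph is part of every optimal solution,
  so `fix_common()` fixes each square that closes a 2-cycle with a
  parallel D-edge.
* **Symmetric squares are score-neutral.**  When a D-edge joins a pair of
  paralogous vertices of a square, or one paralogous pair consists of two
  D-telomeres, or the D-edges at one paralogous pair both lead to
  S-telomeres, the two resolutions are equivalent;
  `fix_symmetric_squares()` fixes such squares to parallel for
  determinism.

## Sigma-4: greedy

After the reductions, the sigma-4 players are valid 2-paths and valid
4-cycles.  Valid 2-paths intersect nothing else; a valid 4-cycle disjoint
from all 2-cycles is always co-optimal, even when two 4-cycles intersect.
`solve_sigma4()` therefore induces players greedily in deterministic
square order (the first of two competing 4-cycles wins), fixes leftover
squares to parallel, and re-scores the assembled solution through
`k_score()` as a self-check.  The traversal order is a free choice — any
order is optimal — and is fixed purely for reproducibility.

## Sigma-6: prune, split, solve

Sigma-6 players are valid {2,4}-paths and valid {4,6}-cycles; players may
intersect and not every player is optimal, so greed fails.  The pipeline:

1. **Pruning** (`prune()`): after separating the 2-cycles, every edge that
   lies in no player among the surviving edges is deleted, to a fixpoint.
   Path-end validity always consults the *original* telomere statuses: an
   endpoint that merely lost its edges to pruning does not fake a
   telomere, so masked fragments are never scored.  Squares whose
   surviving edges sit in one pair are thereby resolved; fully pruned
   squares are fixed arbitrarily.  Pruning preserves the 6-score and
   splits the graph into small components solvable independently.
2. **Classification** (`classify_components()`): a component without
   ambiguous squares must be a single player (a resolved 2/4/6-cycle or
   0/2/4-path) — anything else raises an internal error.  The 6-score is
   `|C| + |P|/2` plus the scores of the ambiguous components.
3. **Triplets** (`detect_triplets()`): the one structure in which a D-edge
   serves four 6-cycles.  Three pairwise D-connected ambiguous squares
   score 2 when saturated (every pair joined by two paralogous D-edges)
   and 1 when one such edge is missing.  Triplets are recognized and
   always resolved by exhausting their at most `2^3` local resolutions.
4. **Bounded components**: any ambiguous component with at most
   `exhaustive_cap` ambiguous squares (default 12) is solved by local
   exhaustion of its resolutions, scored by the same component-local
   decomposition used everywhere else.  This covers, with proof by
   enumeration rather than by case catalogue, all the bounded exceptional
   structures (non-linear cycle-bubbles, which cannot exceed 8 cycles;
   two-cycle bubbles with non-plug connections; and every triplet).
5. **Large cycle-only components** (`straight_bubble_solution()`): in a
   component whose players are all cycles, each candidate S-edge of an
   ambiguous square lies in exactly one player, so one square's choice
   propagates uniquely through its neighbors — the straight solution.  Its
   complement is the only alternative; the better of the two (or either,
   when balanced) is optimal.
6. **Large mixed components** (`build_intersection_graph()` +
   `solve_flows()`): players become vertices weighted 1/2 (paths) or 1
   (cycles), with an edge between intersecting players; a maximum-weight
   independent set is an optimal solution of the component.  The
   structures arising here are chains: path-lines and cyclic lines
   (intersection-graph components of maximum degree two) are solved by the
   linear alternating dynamic program — on an unsaturated line this
   selects exactly the odd-numbered players, and on a cyclic line of odd
   length it drops the last one; double-lines, plug-connected cycle-lines
   and the residual bounded clutter are solved exactly by memoized
   branch-and-reduce with component splitting.  This realizes the same
   optimum as the line/double-line/balanced-link case analysis but with a
   single exact mechanism; the deliberate design choice is to prove
   optimality locally (an exact independent-set solver over exactly the
   players that exist) instead of transcribing a catalogue of bounded
   cases, which the bounded-exhaustion fallback covers anyway.  Structure
   guarantees the solver stays effectively linear: after symmetric squares
   and triplets are gone, a D-edge lies in at most two players and an
   S-edge of an ambiguous square in exactly one, so only line-like and
   bounded components occur.

The assembled solution is independently re-scored through `k_score()` and
compared with the structural account `|C| + |P|/2 + sum sigma_6(M)`; a
disagreement is an internal error, never silently accepted.

## Numerical and determinism choices

* Scores are kept in integer half-units internally; all reported values
  are exact multiples of 1/2.
* Ties are deterministic everywhere: the oracle returns the
  lexicographically smallest maximizer (parallel before crossed, square 1
  most significant); arbitrary fixes use the parallel pair; greedy
  traversal follows square indices; line numbering starts at the smallest
  canonical vertex.
* `exhaustive_cap` trades constant-factor work for case analysis; any
  value at least 3 is correct (components below the cap are exhausted,
  components above it satisfy the structural preconditions).  Setting it
  lower merely routes more components through the structural machinery,
  which the test suite exploits to exercise those paths.
* Degenerate inputs — genomes with no adjacencies, empty components,
  instances whose graph prunes to nothing — flow through the same code
  paths; 0-paths are tracked explicitly as common telomeres.

## The instance generator

`random_singular_genome()` scatters `n` families over the requested
numbers of linear and circular chromosomes with random orientations.
`random_duplicated_from()` emulates the evolutionary scenario behind the
double distance: a whole-genome duplication (one doubling of `S`, each
circular chromosome independently copied or concatenated) followed by
`n_dcj` random DCJ operations, sampled uniformly over adjacencies and
telomeres so that inversions, translocations, fusions, fissions and
telomeric cuts all occur; copy labels are stripped at the end.  Since one
DCJ changes the distance by at most one, `n_dcj` upper-bounds the DCJ
double distance — a property the tests assert.

The generator emulates rearrangement only: gene content is conserved, all
families have exactly two copies in `D`, and there are no unequal family
sizes, gene losses, or sequence-level artifacts.  Passing tests on
generated instances therefore validates the combinatorial optimality of
the solvers, not robustness to annotation noise in real gene-order data.

## Validation strategy and problem sizes

The suite checks the solvers against the exhaustive oracle on more than
five hundred seeded instances stratified over circular-only, linear-only
and mixed genomes with up to about ten free squares, plus constructed
triplets, symmetric squares, and cycle-bubbles; the structural sigma-6
routes are additionally forced (by lowering `exhaustive_cap`) and compared
with the oracle, and the independent-set solver is cross-checked against
brute force on lines, ladders and random weighted graphs.  Scaling runs
use generated instances up to `n* = 10^4` families for k in {2, 4, 6} and
assert that the solvers' operation counts grow linearly with the instance
size.

## Limitations

* Only `k` in {2, 4, 6} is solved polynomially; `k >= 8` and `k = Inf`
  are available through the exponential oracle alone.
* Distances only: no DCJ scenario (operation sequence) is reconstructed.
* Median, halving and guided-halving problems are out of scope.
* The linearity claim is checked by operation counts, not by wall-clock
  certification.
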