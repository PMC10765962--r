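# sigmak

Genome rearrangement distances between gene-order genomes with linear and
circular chromosomes, for comparative genomics after whole-genome
duplication.

Two singular genomes over the same `n*` gene families are compared through
their **breakpoint graph**, whose components are alternating even cycles
and paths.  With `c_i` cycles of `i` edges and `p_j` paths of `j` edges,
the **sigma-k** family of distances

```
d_k = n* − ( c2 + c4 + … + ck  +  (p0 + p2 + … + p(k−2)) / 2 )
```

interpolates between the breakpoint distance (`k = 2`) and the DCJ
(double-cut-and-join) rearrangement distance (`k = ∞`).

The package's core is the **sigma-k double distance**: given a singular
genome `S` and a duplicated genome `D` (the descendant of a whole-genome
duplication), it is the minimum sigma-k distance between `D` and any
doubling of `S`.  The solution space is a binary choice per *square* of
the ambiguous breakpoint graph; `sigmak` implements

* the closed greedy formula for `k = 2`,
* a greedy linear-time algorithm for `k = 4`,
* a linear-time algorithm for `k = 6` (pruning, component splitting,
  triplet handling, straight cycle-bubble propagation, and exact
  maximum-weight independent sets over player intersection graphs),
* a brute-force oracle over all `2^a*` square resolutions, for any even
  `k` and for `k = ∞` (the DCJ double distance, which is NP-hard), used
  to verify the polynomial algorithms on hundreds of seeded instances.

It also ships genome parsing/serialization (a bracket format plus a
UniMoG-style dialect), seeded instance generators emulating a duplication
followed by random DCJ rearrangements, Graphviz export of all graphs, and
a command-line front-end.

## Worked example

The canonical pair `S1 = {(1 -3 2) [4]}`, `S2 = {(1 2) [3 -4]}`:

```r
library(sigmak)
s1 <- parse_genome("(1 -3 2) [4]")[[1]]
s2 <- parse_genome("(1 2) [3 -4]")[[1]]
sigma_distance(s1, s2, 2)
#> [1] 2.5
sigma_distance(s1, s2, Inf)
#> [1] 2
decompose(build_breakpoint_graph(s1, s2))
#> components of a breakpoint graph on 4 families:
#>   cycles: 1x 2-cycle
#>   paths:  1x 0-path, 1x 4-path
```

The pair shares one adjacency (the 2-cycle) and one telomere (the
0-path), hence breakpoint distance `4 − (1 + 1/2) = 2.5`; counting the
4-path as well gives DCJ distance `4 − (1 + 2/2) = 2`.

A double-distance instance — singular `S = {[1 2 3]}` against duplicated
`D = {[1 2 -3 1] [-3 2]}`:

```r
s <- parse_genome("[1 2 3]")[[1]]
d <- parse_genome("[1 2 -3 1] [-3 2]")[[1]]
double_distance(s, d, 2)$distance   # 4    (breakpoint double distance)
double_distance(s, d, 4)$distance   # 3.5
res <- double_distance(s, d, 6)
res$distance                        # 3
res$tau
#> [1] "parallel" "crossed"
```

The returned solution resolves square 1 parallel (inducing the 2-cycle of
the common adjacency `1h 2t`) and square 2 crossed; its induced breakpoint
graph has one 2-cycle, two 0-paths, one 2-path and one 4-path, for a
6-score of `1 + (2 + 1 + 1)/2 = 3` and distance `2·3 − 3 = 3`.

From a shell, the same computations:

```sh
inst/exec/sigmak distance --k 2 A.txt B.txt       # prints 2.5
inst/exec/sigmak double-distance --k 6 S.txt D.txt
inst/exec/sigmak generate --families 50 --dcj 20 --seed 7 --out-s S.txt --out-d D.txt
inst/exec/sigmak graph --which pruned --dot pg.dot S.txt D.txt
```

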