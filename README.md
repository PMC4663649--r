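# phyloterrace

Partial phylogenetic terraces and the conditions under which tree
rearrangements change induced partition trees.

## The problem

In partitioned phylogenomics the score (log-likelihood or parsimony) of a
species tree *T* is the sum of scores of its *induced partition trees*
*T*|*Y<sub>i</sub>*, where *Y<sub>i</sub>* is the set of taxa that actually
have data for partition *i* of the supermatrix.  With sparse supermatrices
(30–70%+ missing data is common), many trees induce exactly the same set of
partition trees — a *terrace* — and many more share a subset of them — a
*partial terrace*.  During a tree search, every partition tree that a
topological rearrangement does **not** change keeps its score, so its
evaluation can be skipped.

`phyloterrace` implements the exact conditions that decide, from set
intersections alone and without rebuilding any restricted tree, whether a
nearest neighbor interchange (NNI), subtree pruning and regrafting (SPR), or
tree bisection and reconnection (TBR) changes each induced partition tree:

* **NNI** around an interior edge with context subtrees *A, B, C, D*:
  *T*|*Y* and *T*<sub>NNI</sub>|*Y* differ **iff** *Y* has at least one taxon
  in each of *A, B, C, D*.  Otherwise RF(*T*|*Y*, *T*<sub>NNI</sub>|*Y*) = 0.
* **SPR** pruning subtree *A* and regrafting along path subtrees
  *B*<sub>1</sub>…*B*<sub>n</sub>: changed iff *Y* meets *A* and at least
  three of the *B<sub>i</sub>*.  When changed, the induced move on *T*|*Y*
  is itself an SPR, pruning *A*∩*Y* and regrafting onto
  *B<sub>k</sub>*∩*Y* with *k* = max{*i* : *B<sub>i</sub>*∩*Y* ≠ ∅} — a long
  SPR on the species tree is typically a short SPR (often an NNI) on the
  partition tree.
* **TBR** bisecting an edge with side subtrees *B*<sub>1..n</sub> and
  *C*<sub>1..m</sub>: changed iff one side has ≥ 1 and the other ≥ 3
  represented subtrees (the 2-and-2 configuration never changes the
  partition tree).  The induced TBR cuts
  (∪*B<sub>i</sub>*)∩*Y* | (∪*C<sub>j</sub>*)∩*Y* and reconnects at
  *B<sub>k</sub>*∩*Y* and *C<sub>h</sub>*∩*Y*.

Around this core the package provides split-set machinery for unrooted
binary trees (Robinson–Foulds distance as the symmetric difference of split
sets, restriction *T*|*Y* via the induced-split formula), move enumeration
and application with the closed-form RF identities
RF(*T*, *T*<sub>NNI</sub>) = 2, RF(*T*, *T*<sub>SPR</sub>) = 2(*n*−2),
RF(*T*, *T*<sub>TBR</sub>) = 2(*n*+*m*−4), partial-terrace binning of NNI
neighborhoods (bins No-PT, PT1–PT10, full terrace over the shared-partition
percentage), Yule–Harding random trees, random coverage matrices, and
synthetic supermatrices.

It is aimed at developers of partitioned tree-search software and at anyone
studying how missing-data structure creates (partial) terraces.

## Worked example

```r
library(phyloterrace)

cov  <- random_coverage(24, 8, 0.45, seed = 101)   # 24 taxa x 8 partitions
tree <- yule_harding_tree(24, taxa = rownames(cov), seed = 101)

s <- nni_neighborhood_summary(tree, cov)
s
#> NNI neighborhood: 42 neighbors, 8 partitions
#>        NO_PT          PT1          PT2          PT3          PT4          PT5
#>         4.76         0.00         4.76         9.52         9.52        14.29
#>          PT6          PT7          PT8          PT9         PT10 FULL_TERRACE
#>         0.00        38.10         4.76         4.76         0.00         9.52
#> Mean shared fraction: 0.5476 (potential savings 54.8%)
```

Every one of the 42 NNI neighbors (2(*n*−3) for *n* = 24) was compared with
the tree using only the intersection predicates.  9.5% of neighbors lie on a
full terrace (identical induced partition trees for all 8 partitions: their
total score is already known), and on average 54.8% of partition-tree
evaluations in this neighborhood could be skipped — the savings estimate.

```r
mv <- enumerate_nni_moves(tree)[[1]]
compare_trees_fast(tree, mv, cov)
#> Shared partition trees: 2 / 8 (25.0%) -> bin PT3

nni_changes_partition(mv, partition_taxa(cov, 1), "p1")
#> Partition p1 : CHANGED (CHANGED)
```

The slow route (`compare_trees()` on `apply_nni(tree, mv)`, restricting
both trees partition by partition) returns the same answer; the test suite
holds the two routes equal on hundreds of randomized instances.

## Command line

```sh
exec/terracetool simulate --taxa 128 --partitions 32 --missing 0.30 \
    --seed 42 --out sim
exec/terracetool neighborhood --tree sim_tree_1.nwk \
    --coverage sim_coverage.tsv --out nb
exec/terracetool check-move --tree sim_tree_1.nwk \
    --coverage sim_coverage.tsv --nni t001,t017 --json
exec/terracetool compare --tree1 a.nwk --tree2 b.nwk --coverage cov.tsv
```

`neighborhood` writes one TSV row per neighbor (move, shared count,
fraction, bin) and a bin-percentage summary; `check-move` reports each
partition as changed/unchanged with a reason code and, for SPR/TBR, the
induced move's splits.  Inputs can be a coverage TSV or an alignment
(FASTA / relaxed PHYLIP) plus a RAxML-style partition file, from which
presence/absence is extracted (a taxon counts as present in a partition if
its block has at least one character outside `? - N X .`).

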