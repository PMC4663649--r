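---
title: "Partial terraces and rearrangement conditions for partitioned supermatrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial terraces and rearrangement conditions for partitioned supermatrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloterrace)
```

## The model

A partitioned phylogenomic analysis scores a species tree $T$ on taxon set
$X$ as a sum over partitions: each partition $i$ covers a taxon subset
$Y_i \subseteq X$ (the taxa with data in that block of the supermatrix), and
contributes the score of the *induced partition tree* $T|Y_i$ — the tree
obtained by keeping only the leaves in $Y_i$ and suppressing degree-2
nodes.  Formally, the split set of $T|Y$ is

$$\Sigma(T|Y) = \{\, A\cap Y \mid B\cap Y \;:\; A|B \in \Sigma(T),\;
A\cap Y \neq \emptyset,\; B\cap Y \neq \emptyset \,\},$$

taken with set semantics (distinct edges of $T$ whose splits project to the
same restricted split contribute one split; the package deduplicates, which
is also what the suppression of degree-2 nodes produces).  Two trees are
topologically equivalent iff their split sets coincide
(splits-equivalence theorem), and the Robinson–Foulds (RF) distance is the
cardinality of the symmetric difference of split sets.

Tree searches move through tree space by NNI, SPR and TBR rearrangements.
Each such move changes a known family of splits expressible in the move's
*context subtrees*:

* an NNI around interior edge $e$ with incident subtree taxon sets
  $A,B,C,D$ replaces $A\cup B\,|\,C\cup D$ by $A\cup D\,|\,B\cup C$
  (RF $=2$);
* an SPR pruning $A$ and regrafting past path subtrees $B_1,\dots,B_n$
  changes the $n-2$ path splits and creates one new split (RF $=2(n-2)$);
* a TBR bisecting $e$ with side subtrees $B_1..B_n$ and $C_1..C_m$ keeps
  $e$'s split and changes the path splits on both sides
  (RF $=2(n+m-4)$).

Because restriction distributes over these families, whether $T|Y$ changes
depends only on which context subtrees $Y$ intersects:

| move | $T|Y$ changes iff | induced move on $T|Y$ |
|------|-------------------|------------------------|
| NNI  | $Y$ meets all of $A,B,C,D$ | the corresponding NNI |
| SPR  | $Y$ meets $A$ and $\ge 3$ of $B_1..B_n$ | SPR pruning $A\cap Y$, regrafting at $B_k\cap Y$, $k=\max\{i: B_i\cap Y\neq\emptyset\}$ |
| TBR  | one side $\ge 1$, other side $\ge 3$ represented | TBR cutting $(\cup B_i)\cap Y \mid (\cup C_j)\cap Y$, reconnecting at $B_k\cap Y$ and $C_h\cap Y$ |

The "if" directions follow from the split algebra; the package implements
all three as exact characterizations ("iff") and pins that choice with a
brute-force oracle suite (restrict both trees, compare split sets) over
randomized trees, moves and subsets.  The necessity argument is the quartet
structure: with fewer represented subtrees than the table requires, every
changed split projects onto a split shared by both restricted trees.

Two species trees belong to one **full terrace** when all their induced
partition trees coincide, and to a **partial terrace** when a proper subset
coincides.  Shared partition trees keep their score, so the shared fraction
bounds the computation a terrace-aware search can skip.

## Degenerate and boundary cases

* Restrictions to 1–3 taxa have no non-trivial splits; such partitions are
  unconditionally "unchanged" and are reported with the distinct reason
  code `TOO_FEW_TAXA` so users can audit them.  The intersection predicates
  are consistent with this automatically (their conditions need at least
  four represented subtrees' worth of taxa).
* An induced TBR whose B side has exactly one represented subtree collapses:
  the reconnect split coincides with the cut split, and the move is applied
  as the equivalent SPR on $T|Y$ (`apply_induced_move()` handles this).
* $n=3$ SPRs and $\{n,m\}=\{2,3\}$ TBRs are flagged NNI-equivalent;
  $m=2$, $n>3$ TBRs SPR-equivalent.  Identity placements (SPR regraft
  adjacent to the attachment; TBR with both reconnect edges adjacent to the
  bisection) are rejected at build time.
* Moves are value objects bound to a topology fingerprint; applying a move
  to a tree with a different split set is a detected error, preventing
  silent misapplication during neighborhood sweeps.

## Numerical and representational choices

Splits are stored as sorted integer rank vectors over a fixed taxon index,
canonicalized to the side *not* containing the smallest-rank taxon present
in the tree, so `A|B` and `B|A` compare equal and split keys hash across
trees.  (A global "rank 0" anchor cannot serve restricted trees that lack
that taxon, hence the per-tree anchor.)  All equivalence tests are split-set
tests; node identity never matters.  Split extraction is a single postorder
pass per tree and is cached, so RF distances and repeated restrictions stay
cheap inside neighborhood sweeps; the fast predicates themselves never build
a restricted tree.

Partial-terrace bins over the shared-partition percentage are: No-PT at
exactly 0%, PT$q$ covering $((q-1)\cdot 10\%,\; q\cdot 10\%]$ for
$q=1..9$, PT10 covering $(90\%, 100\%)$ — open at 100% — and full terrace
at exactly 100%.  The decade bins are right-closed while PT10 is open at
both ends' top; the bin of a count pair is decided in integer arithmetic
(`ceil(10·shared/total)`), never floating point, so boundary fractions like
$3/30$ land deterministically.  The savings estimate weighs all partitions
equally; an optional per-partition weight vector (e.g. alignment lengths)
generalizes the fraction, in which case the bin is computed from the
weighted fraction numerically.

Newick output is deterministic: the tree is serialized rooted at the
internal node adjacent to its smallest-rank leaf with children ordered by
smallest contained rank, so equivalent trees on one taxon index print
identically.  Edge lengths are parsed, keyed by their edge's split, and
re-emitted on round trip, but rearrangement and restriction outputs are
topology-only and carry no lengths.

## What the generator emulates

`yule_harding_tree()` implements random-branching (equal-rates) growth: a
uniformly chosen pendant edge is split to attach each next taxon, the tree
is left unrooted, and labels are randomly permuted.  On four taxa the three
unrooted topologies are equiprobable, which the suite checks by a
chi-squared test at $\alpha = 0.01$ on 3000 draws.

`random_coverage()` draws i.i.d. presence with probability
$1-\text{missing}$ and then repairs the grid to meet two constraints —
each partition keeps at least `min_partition_taxa` (default 4, the smallest
set with any non-trivial topology) present taxa, each taxon at least one
partition — by flipping the fewest absent cells (column deficits are filled
preferentially in all-absent rows, which attains the minimum; verified
against exhaustive search on small grids).  Taxa covered by no partition in
user-supplied matrices are dropped with a warning rather than an error,
since wild sparse supermatrices contain such rows.  Default study
conditions in the tests and end-to-end runs use 30–80% missing data on
grids up to 128 taxa × 32 partitions, matching the sparsity regimes of
published supermatrices.

`synthetic_supermatrix()` writes uniform random A/C/G/T for present cells
and `?` blocks for absent ones.  Sequence content is deliberately
model-free: nothing downstream reads anything but presence/absence, so no
substitution model is simulated.  What these synthetic data do **not**
emulate: phylogenetic signal, rate heterogeneity, or the correlated
(clade-structured) missingness of real supermatrices — passing tests show
the combinatorial machinery is exact, not that any particular biological
dataset will show a given savings percentage.

## Problem sizes used by the checks

The oracle suites run on trees of 6–40 taxa with 500 random
(tree, move, subset) triples per move kind; the end-to-end run simulates
128 taxa × 32 partitions at 30% missing data, evaluates the full NNI
neighborhood (250 neighbors) with the fast predicates, and reconciles a
10-neighbor subsample against the slow restrict-and-compare route.  These
sizes exercise every code path at desk scale while keeping the whole suite
in a couple of minutes.

## Known limitations

* Terrace *enumeration* (listing all trees on a terrace) is out of scope;
  the package decides membership and partial overlap for given trees and
  moves.
* Likelihood and parsimony scoring are not computed; the edge-relevance
  predicate (`edge_affects_partition()`) exposes the skip condition for
  edge-length optimization under edge-linked models but no optimizer is
  included.
* Multifurcating trees are parseable behind an explicit flag, but the move
  machinery requires binary trees and fails fast on polytomies.
* Codon-interleaved partition ranges (`1-100\3`) are rejected rather than
  parsed.
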