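Package: phyloterrace
Title: Partial Phylogenetic Terraces and Rearrangement Conditions for
    Partitioned Supermatrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decides, without recomputing induced partition trees, whether a
    nearest neighbor interchange (NNI), subtree pruning and regrafting (SPR)
    or tree bisection and reconnection (TBR) rearrangement of a species tree
    changes the topology of each induced partition tree of a sparse
    phylogenomic supermatrix.  Provides split-set machinery for unrooted
    binary trees (Robinson-Foulds distance, restriction to taxon subsets),
    enumeration and application of the three rearrangements with resolved
    context subtrees, the mapping of a species-tree move to the induced move
    on a partition tree, partial-terrace comparison and binning of NNI
    neighborhoods with computational-savings estimates, Yule-Harding random
    trees and random coverage matrices for simulation, and a command-line
    interface over Newick trees, FASTA/relaxed-PHYLIP alignments with
    RAxML-style partition files, and coverage tables.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
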