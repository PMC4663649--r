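# Synthetic data: Yule-Harding random trees, random coverage matrices and
# synthetic supermatrices.  Everything is seed-deterministic so that every
# other module is testable without external data.

#' Generate a Yule-Harding random tree
#'
#' Random-branching (equal-rates) growth: starting from a two-leaf tree, the
#' next taxon is attached to a uniformly chosen pendant edge (equivalently,
#' a uniformly chosen current leaf is split), the tree is left unrooted and
#' the taxon labels are randomly permuted over the leaves.  On four taxa
#' this makes the three unrooted topologies equiprobable.
#'
#' @param n_taxa Number of leaves (`>= 3`).
#' @param taxa Optional [taxon_index()] or label vector of length `n_taxa`;
#'   default labels are zero-padded `t01, t02, ...`.
#' @param seed Optional integer seed (the caller's RNG state is restored).
#' @return A binary unrooted `phylo_tree`.
#' @examples
#' yule_harding_tree(8, seed = 1)
#' @export
yule_harding_tree <- function(n_taxa, taxa = NULL, seed = NULL) {
  n_taxa <- as.integer(n_taxa)
  if (n_taxa < 3L) stop("a Yule-Harding tree needs at least 3 taxa")
  if (is.null(taxa)) {
    taxa <- taxon_index(sprintf("t%0*d", nchar(n_taxa), seq_len(n_taxa)))
  } else {
    taxa <- taxon_index(taxa)
    if (length(taxa) != n_taxa) stop("need exactly one label per leaf")
  }
  with_seed(seed, {
    N <- 2L * n_taxa - 2L
    adj <- vector("list", N)
    adj[[1L]] <- 2L; adj[[2L]] <- 1L
    leaf_nodes <- c(1L, 2L)
    next_id <- 3L
    for (i in 3L:n_taxa) {
      ell <- leaf_nodes[sample.int(length(leaf_nodes), 1L)]
      p <- adj[[ell]][1L]
      mid <- next_id; tip <- next_id + 1L
      next_id <- next_id + 2L
      adj[[p]][adj[[p]] == ell] <- mid
      adj[[ell]] <- mid
      adj[[mid]] <- c(p, ell, tip)
      adj[[tip]] <- mid
      leaf_nodes <- c(leaf_nodes, tip)
    }
    leaf_rank <- rep(NA_integer_, N)
    leaf_rank[leaf_nodes] <- sample.int(n_taxa)
    canonical_tree(taxa, leaf_rank, adj)
  })
}

#' Generate a random coverage matrix
#'
#' Cells are present independently with probability `1 - missing_fraction`,
#' then repaired to satisfy the per-partition minimum and the at-least-one-
#' partition-per-taxon constraint by flipping the fewest absent cells
#' possible (column deficits are filled preferentially in all-absent rows,
#' which provably attains the minimum).
#'
#' @param n_taxa,n_partitions Grid dimensions.
#' @param missing_fraction Target fraction of absent cells in `[0, 1)`.
#' @param seed Optional integer seed.
#' @param min_partition_taxa Minimum present taxa per partition (default 4,
#'   the smallest taxon set with a non-trivial topology).
#' @param taxa,partitions Optional row/column names.
#' @return A `coverage_matrix`.
#' @export
random_coverage <- function(n_taxa, n_partitions, missing_fraction,
                            seed = NULL, min_partition_taxa = 4L,
                            taxa = NULL, partitions = NULL) {
  n_taxa <- as.integer(n_taxa); n_partitions <- as.integer(n_partitions)
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop("missing_fraction must be in [0, 1)")
  }
  if (min_partition_taxa > n_taxa) {
    stop("infeasible: min_partition_taxa exceeds the number of taxa")
  }
  if (is.null(taxa)) {
    taxa <- sprintf("t%0*d", nchar(n_taxa), seq_len(n_taxa))
  }
  if (is.null(partitions)) {
    partitions <- sprintf("p%0*d", nchar(n_partitions), seq_len(n_partitions))
  }
  with_seed(seed, {
    m <- matrix(stats::runif(n_taxa * n_partitions) >= missing_fraction,
                nrow = n_taxa, dimnames = list(taxa, partitions))
    coverage_matrix(repair_coverage(m, min_partition_taxa))
  })
}

# Flip the fewest absent cells so that every partition has at least
# `min_partition_taxa` present taxa and every taxon at least one partition.
# Column deficits are filled preferentially in all-absent rows; any column
# flip placed in an empty row serves both constraints, and the complete
# bipartite structure of the choice makes the greedy assignment minimal.
repair_coverage <- function(m, min_partition_taxa) {
  for (j in seq_len(ncol(m))) {
    d <- min_partition_taxa - sum(m[, j])
    if (d <= 0L) next
    absent <- which(!m[, j])
    empty_first <- order(rowSums(m)[absent] > 0, stats::runif(length(absent)))
    m[absent[empty_first[seq_len(d)]], j] <- TRUE
  }
  for (i in which(rowSums(m) == 0)) {
    m[i, sample.int(ncol(m), 1L)] <- TRUE
  }
  m
}

#' Emit a synthetic supermatrix matching a coverage matrix
#'
#' Builds an alignment whose block for partition `i` is uniform random
#' A/C/G/T of length `part_len` where the taxon is present and `'?'` (the
#' unknown-character convention for missing data) where it is absent, plus a
#' RAxML-style partition file of contiguous ranges.  Sequence content is
#' irrelevant to every downstream computation except presence/absence, so no
#' substitution model is simulated.  Coverage extracted from the output by
#' [extract_coverage()] reproduces `cov` cell for cell.
#'
#' @param tree A `phylo_tree` on the coverage's taxa (consistency check
#'   only).
#' @param cov A `coverage_matrix`.
#' @param part_len Sites per partition (`>= 1`).
#' @param seed Optional integer seed.
#' @param format `"fasta"` (default) or `"phylip"` (relaxed).
#' @return A list with elements `alignment` and `partitions`, both single
#'   strings ready to be written to files.
#' @export
synthetic_supermatrix <- function(tree, cov, part_len = 100L, seed = NULL,
                                  format = c("fasta", "phylip")) {
  format <- match.arg(format)
  part_len <- as.integer(part_len)
  if (part_len < 1L) stop("part_len must be >= 1")
  if (!setequal(leaf_labels(tree), rownames(cov))) {
    stop("tree taxa and coverage taxa differ")
  }
  with_seed(seed, {
    P <- ncol(cov)
    taxa <- rownames(cov)
    blocks <- matrix("", nrow = length(taxa), ncol = P)
    gap <- strrep("?", part_len)
    for (j in seq_len(P)) {
      for (i in seq_along(taxa)) {
        blocks[i, j] <- if (cov[i, j]) {
          paste(sample(c("A", "C", "G", "T"), part_len, replace = TRUE),
                collapse = "")
        } else gap
      }
    }
    seqs <- apply(blocks, 1L, paste, collapse = "")
    aln <- if (format == "fasta") {
      paste0(paste0(">", taxa, "\n", seqs, collapse = "\n"), "\n")
    } else {
      paste0(length(taxa), " ", P * part_len, "\n",
             paste0(taxa, "  ", seqs, collapse = "\n"), "\n")
    }
    parts <- paste0(
      paste0("DNA, ", colnames(cov), " = ",
             (seq_len(P) - 1L) * part_len + 1L, "-", seq_len(P) * part_len,
             collapse = "\n"), "\n")
    list(alignment = aln, partitions = parts)
  })
}
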