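# Partial/full terrace comparison of trees under a coverage matrix,
# shared-partition-tree binning, and NNI-neighborhood summaries.

BIN_LEVELS <- c("NO_PT", paste0("PT", 1:10), "FULL_TERRACE")

#' Construct a coverage matrix
#'
#' A coverage matrix records which taxa have sequence data for which
#' partitions of a supermatrix; column `i`'s present taxa form the
#' partition's taxon set `Y_i`.  Taxa present in no partition are dropped
#' with a warning (they cannot inform any partition tree); a partition with
#' no present taxon is an error.
#'
#' @param x A logical or 0/1 matrix, taxa in rows (rownames required),
#'   partitions in columns (colnames optional, default `p1, p2, ...`).
#' @return An object of class `coverage_matrix` (a logical matrix).
#' @export
coverage_matrix <- function(x) {
  m <- as.matrix(x)
  if (is.numeric(m)) {
    if (!all(m %in% c(0, 1))) stop("coverage cells must be 0/1 or logical")
    m <- m == 1
  }
  if (!is.logical(m)) stop("coverage cells must be 0/1 or logical")
  if (is.null(rownames(m))) stop("coverage matrix needs taxon rownames")
  if (is.null(colnames(m))) colnames(m) <- paste0("p", seq_len(ncol(m)))
  if (anyDuplicated(rownames(m))) stop("duplicate taxon names")
  if (anyDuplicated(colnames(m))) stop("duplicate partition names")
  empty_part <- colSums(m) == 0
  if (any(empty_part)) {
    stop("partition(s) with no present taxon: ",
         paste(colnames(m)[empty_part], collapse = ", "))
  }
  uncovered <- rowSums(m) == 0
  if (any(uncovered)) {
    warning("dropping taxa covered by no partition: ",
            paste(rownames(m)[uncovered], collapse = ", "))
    m <- m[!uncovered, , drop = FALSE]
  }
  structure(m, class = c("coverage_matrix", "matrix"))
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat("Coverage matrix:", nrow(x), "taxa x", ncol(x), "partitions;",
      sprintf("missing %.1f%%\n", 100 * (1 - mean(x))))
  invisible(x)
}

#' Taxon set of one partition
#' @param cov A `coverage_matrix`.
#' @param partition Column name or index.
#' @return Character vector of the taxa present in the partition.
#' @export
partition_taxa <- function(cov, partition) {
  rownames(cov)[cov[, partition]]
}

#' Fraction of missing cells in a coverage matrix
#' @param cov A `coverage_matrix`.
#' @return Number in `[0, 1)`.
#' @export
missing_fraction <- function(cov) 1 - mean(cov)

# ---------------------------------------------------------------------------

#' Partial-terrace bin of a shared-partition count
#'
#' Bins follow the shared-partition-tree percentage: `NO_PT` for exactly 0%,
#' `PTq` for the interval `((q-1)*10%, q*10%]` with `q = 1..9`, `PT10` for
#' `(90%, 100%)` (open at 100%), and `FULL_TERRACE` for exactly 100%.
#' Boundaries are decided in exact integer arithmetic on
#' `(shared, total)`, never floating point.
#'
#' @param shared Number of shared induced partition trees.
#' @param total Total number of partitions (`>= 1`).
#' @return One of `"NO_PT"`, `"PT1"`..`"PT10"`, `"FULL_TERRACE"`.
#' @examples
#' classify_bin(3, 30)   # exactly 10% -> "PT1"
#' classify_bin(31, 32)  # ~96.9% -> "PT10"
#' @export
classify_bin <- function(shared, total) {
  shared <- as.integer(shared); total <- as.integer(total)
  if (is.na(total) || total < 1L) stop("total must be >= 1")
  if (is.na(shared) || shared < 0L || shared > total) {
    stop("shared must be between 0 and total")
  }
  if (shared == 0L) return("NO_PT")
  if (shared == total) return("FULL_TERRACE")
  q <- (10L * shared + total - 1L) %/% total   # ceil(10 * shared / total)
  paste0("PT", q)
}

# Numeric variant for weighted fractions (weights need not be integer).
classify_bin_numeric <- function(fraction) {
  if (fraction <= 0) return("NO_PT")
  if (fraction >= 1) return("FULL_TERRACE")
  q <- min(10L, as.integer(ceiling(fraction * 10 - 1e-9)))
  paste0("PT", max(1L, q))
}

new_pair_comparison <- function(per_partition, reasons, weights = NULL) {
  total <- length(per_partition)
  shared <- sum(per_partition)
  if (is.null(weights)) {
    fraction <- shared / total
    bin <- classify_bin(shared, total)
  } else {
    fraction <- sum(weights[per_partition]) / sum(weights)
    bin <- classify_bin_numeric(fraction)
  }
  structure(list(per_partition = per_partition,
                 reasons = reasons,
                 shared_count = shared,
                 total_partitions = total,
                 fraction = fraction,
                 bin = bin,
                 weights = weights),
            class = "pair_comparison")
}

#' @export
print.pair_comparison <- function(x, ...) {
  cat(sprintf("Shared partition trees: %d / %d (%.1f%%) -> bin %s\n",
              x$shared_count, x$total_partitions, 100 * x$fraction, x$bin))
  invisible(x)
}

check_cov_trees <- function(t1, t2, cov) {
  check_same_leaves(t1, t2)
  labs <- leaf_labels(t1)
  miss <- setdiff(rownames(cov), labs)
  if (length(miss)) {
    stop("coverage matrix has taxa absent from the trees: ",
         paste(miss, collapse = ", "))
  }
}

#' Compare two trees partition by partition (slow path)
#'
#' For each partition `i` with taxon set `Y_i`, the induced partition trees
#' `t1|Y_i` and `t2|Y_i` are built and compared for topological
#' equivalence.  Two trees on one full terrace share all induced partition
#' trees; sharing only a subset places them on a partial terrace.
#' Partitions whose taxon set restricted to the trees has at most 3 taxa
#' have no non-trivial splits and always count as shared (reason
#' `TOO_FEW_TAXA`).
#'
#' @param t1,t2 Trees on the coverage matrix's taxon set (extra tree taxa
#'   are allowed and ignored; they correspond to taxa dropped from the
#'   coverage).
#' @param cov A `coverage_matrix`.
#' @param weights Optional positive per-partition weights (e.g. alignment
#'   lengths) used for the shared fraction; the default weights all
#'   partitions equally.
#' @return A `pair_comparison`.
#' @export
compare_trees <- function(t1, t2, cov, weights = NULL) {
  check_cov_trees(t1, t2, cov)
  P <- ncol(cov)
  shared <- logical(P)
  reasons <- character(P)
  for (j in seq_len(P)) {
    y <- partition_taxa(cov, j)
    if (length(y) <= 3L) {
      shared[j] <- TRUE
      reasons[j] <- "TOO_FEW_TAXA"
    } else {
      shared[j] <- trees_equivalent(restrict_tree(t1, y),
                                    restrict_tree(t2, y))
      reasons[j] <- if (shared[j]) "UNCHANGED" else "CHANGED"
    }
  }
  names(shared) <- names(reasons) <- colnames(cov)
  new_pair_comparison(shared, reasons, check_weights(weights, cov))
}

check_weights <- function(weights, cov) {
  if (is.null(weights)) return(NULL)
  if (length(weights) != ncol(cov) || any(!is.finite(weights)) ||
      any(weights <= 0)) {
    stop("weights must be positive, one per partition")
  }
  weights
}

#' Compare a tree against a rearranged neighbor (fast path)
#'
#' Produces the same result as
#' `compare_trees(tree, apply_move(tree, move), cov)` but decides each
#' partition with the intersection-emptiness predicates
#' ([nni_changes_partition()] and friends) instead of building restricted
#' trees — the point of the partial-terrace conditions is precisely to skip
#' that recomputation during tree search.
#'
#' @param tree The current species tree.
#' @param move A move built on `tree`.
#' @param cov A `coverage_matrix`.
#' @inheritParams compare_trees
#' @return A `pair_comparison`.
#' @export
compare_trees_fast <- function(tree, move, cov, weights = NULL) {
  check_move(tree, move)
  P <- ncol(cov)
  shared <- logical(P)
  reasons <- character(P)
  for (j in seq_len(P)) {
    y <- which_cov_mask(tree, cov, j)
    rep <- switch(move$kind,
                  NNI = nni_changes_partition(move, y, colnames(cov)[j]),
                  SPR = spr_changes_partition(move, y, colnames(cov)[j]),
                  TBR = tbr_changes_partition(move, y, colnames(cov)[j]))
    shared[j] <- !rep$changed
    reasons[j] <- rep$reason
  }
  names(shared) <- names(reasons) <- colnames(cov)
  new_pair_comparison(shared, reasons, check_weights(weights, cov))
}

# Partition taxon set as a mask over the tree's taxon index.
which_cov_mask <- function(tree, cov, j) {
  mask <- logical(length(tree$taxa))
  mask[taxon_ranks(tree$taxa, partition_taxa(cov, j))] <- TRUE
  mask
}

# ---------------------------------------------------------------------------

#' Summarize the NNI neighborhood of a tree under a coverage matrix
#'
#' Enumerates all `2(n-3)` NNI neighbors, evaluates each against the tree
#' with the fast predicates (one neighbor at a time; memory stays flat), and
#' tabulates the neighbors into the partial-terrace bins along with the mean
#' shared-partition-tree fraction.
#'
#' @param tree A binary `phylo_tree` on the coverage's taxa.
#' @param cov A `coverage_matrix`.
#' @inheritParams compare_trees
#' @return An object of class `neighborhood_summary`: a list with a
#'   per-neighbor data frame (`neighbors`), `bin_counts`, `bin_percent`,
#'   `mean_shared_fraction`, `neighborhood_size` and `n_partitions`.
#' @export
nni_neighborhood_summary <- function(tree, cov, weights = NULL) {
  moves <- enumerate_nni_moves(tree)
  nmv <- length(moves)
  rows <- vector("list", nmv)
  for (i in seq_len(nmv)) {
    pc <- compare_trees_fast(tree, moves[[i]], cov, weights)
    rows[[i]] <- data.frame(
      edge = moves[[i]]$edge_key_labels,
      exchange = moves[[i]]$exchange,
      shared = pc$shared_count,
      total = pc$total_partitions,
      fraction = pc$fraction,
      bin = pc$bin,
      stringsAsFactors = FALSE)
  }
  nb <- do.call(rbind, rows)
  counts <- table(factor(nb$bin, levels = BIN_LEVELS))
  structure(list(neighbors = nb,
                 bin_counts = counts,
                 bin_percent = 100 * as.numeric(counts) / nmv,
                 mean_shared_fraction = mean(nb$fraction),
                 neighborhood_size = nmv,
                 n_partitions = ncol(cov)),
            class = "neighborhood_summary")
}

#' @export
print.neighborhood_summary <- function(x, ...) {
  cat("NNI neighborhood:", x$neighborhood_size, "neighbors,",
      x$n_partitions, "partitions\n")
  pct <- sprintf("%.2f", x$bin_percent)
  names(pct) <- BIN_LEVELS
  print(pct, quote = FALSE)
  cat(sprintf("Mean shared fraction: %.4f (potential savings %.1f%%)\n",
              x$mean_shared_fraction, savings_estimate(x)))
  invisible(x)
}

#' Potential computational-savings estimate
#'
#' The mean fraction of induced partition trees shared between the tree and
#' its NNI neighbors, as a percentage: the fraction of partition-tree
#' evaluations a terrace-aware tree search could skip in this neighborhood.
#' Partitions are weighted equally unless the summary was built with
#' weights.
#'
#' @param summary A `neighborhood_summary`.
#' @return A percentage in `[0, 100]`.
#' @export
savings_estimate <- function(summary) {
  stopifnot(inherits(summary, "neighborhood_summary"))
  100 * summary$mean_shared_fraction
}

#' Write neighborhood reports as TSV
#'
#' `neighbors_path` receives one row per NNI neighbor (move descriptor,
#' shared count, total, fraction, bin); `summary_path` receives one row of
#' bin percentages (columns `No_PT`, `PT1`..`PT10`, `Full_terrace`) plus
#' the mean shared fraction and the neighbor count per bin.
#'
#' @param summary A `neighborhood_summary`.
#' @param neighbors_path,summary_path Output file paths (`NULL` to skip).
#' @return `summary`, invisibly.
#' @export
write_neighborhood_tsv <- function(summary, neighbors_path = NULL,
                                   summary_path = NULL) {
  if (!is.null(neighbors_path)) {
    utils::write.table(summary$neighbors, neighbors_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(summary_path)) {
    df <- data.frame(
      bin = c("No_PT", paste0("PT", 1:10), "Full_terrace"),
      count = as.integer(summary$bin_counts),
      percent = summary$bin_percent)
    df <- rbind(df, data.frame(bin = "Mean_shared_fraction", count = NA,
                               percent = 100 * summary$mean_shared_fraction))
    utils::write.table(df, summary_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(summary)
}

# ---------------------------------------------------------------------------
# Coverage TSV I/O: taxon rows, partition columns, 0/1 cells, header row.

#' Read a coverage matrix from TSV
#' @param path TSV file: header row of partition names, first column taxon
#'   names, cells 0/1.
#' @return A `coverage_matrix`.
#' @export
read_coverage <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  coverage_matrix(as.matrix(df))
}

#' Write a coverage matrix to TSV
#' @param cov A `coverage_matrix`.
#' @param path Output path.
#' @return `cov`, invisibly.
#' @export
write_coverage <- function(cov, path) {
  m <- matrix(as.integer(cov), nrow = nrow(cov), dimnames = dimnames(cov))
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cov)
}
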