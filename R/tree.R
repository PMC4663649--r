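# Unrooted leaf-labeled trees.
#
# A `phylo_tree` is an undirected adjacency-list representation of an
# unrooted tree whose leaves are labeled by taxa from a shared taxon index:
#   taxa    - character vector, the taxon index of the analysis
#   leaves  - strictly increasing integer ranks into `taxa`; leaf node i of
#             the tree carries taxon rank leaves[i]
#   adj     - list of integer neighbor vectors; nodes 1..k are leaves,
#             nodes k+1..N internal
#   edge_lengths - optional named numeric, names are canonical split keys
# Topological comparisons never look at node identity, only at split sets.

new_phylo_tree <- function(taxa, leaves, adj, edge_lengths = NULL,
                           binary = TRUE) {
  tr <- structure(
    list(taxa = as.character(taxa),
         leaves = as.integer(leaves),
         adj = adj,
         n_leaf = length(leaves),
         edge_lengths = edge_lengths,
         cache = new.env(parent = emptyenv())),
    class = "phylo_tree")
  if (!binary) attr(tr, "polytomies") <- TRUE
  validate_phylo_tree(tr, binary = binary)
  tr
}

#' Test for a phylo_tree object
#' @param x An object.
#' @return `TRUE` if `x` is a `phylo_tree`.
#' @export
is_phylo_tree <- function(x) inherits(x, "phylo_tree")

validate_phylo_tree <- function(tree, binary = TRUE) {
  k <- tree$n_leaf
  N <- length(tree$adj)
  if (k < 1L) stop("tree must have at least one leaf")
  if (is.unsorted(tree$leaves, strictly = TRUE)) {
    stop("leaf ranks must be strictly increasing")
  }
  if (any(tree$leaves < 1L) || any(tree$leaves > length(tree$taxa))) {
    stop("leaf rank outside taxon index")
  }
  deg <- lengths(tree$adj)
  if (k == 1L) {
    if (N != 1L || deg[1L] != 0L) stop("malformed single-leaf tree")
    return(invisible(tree))
  }
  if (binary && N != 2L * k - 2L && !(k == 2L && N == 2L)) {
    stop("binary unrooted tree with ", k, " leaves must have ",
         if (k == 2L) 2L else 2L * k - 2L, " nodes, found ", N)
  }
  if (any(deg[seq_len(k)] != 1L)) stop("leaf nodes must have degree 1")
  if (k >= 3L) {
    bad <- if (binary) any(deg[(k + 1L):N] != 3L) else
      any(deg[(k + 1L):N] < 3L)
    if (bad) {
      stop("internal nodes must have degree 3 (bifurcating unrooted tree)")
    }
  }
  # symmetry and connectivity
  for (u in seq_len(N)) {
    for (v in tree$adj[[u]]) {
      if (!(u %in% tree$adj[[v]])) stop("adjacency not symmetric")
    }
  }
  seen <- logical(N)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (v in tree$adj[[u]]) {
      if (!seen[v]) {
        seen[v] <- TRUE
        stack <- c(stack, v)
      }
    }
  }
  if (!all(seen)) stop("tree is not connected")
  invisible(tree)
}

#' Leaf labels of a tree
#' @param tree A `phylo_tree`.
#' @return Character vector of the tree's leaf labels, in rank order.
#' @export
leaf_labels <- function(tree) tree$taxa[tree$leaves]

#' @export
print.phylo_tree <- function(x, ...) {
  cat("Unrooted phylogenetic tree with", x$n_leaf, "leaves",
      sprintf("(%d edges)\n", n_edges(x)))
  labs <- leaf_labels(x)
  if (length(labs) > 8L) labs <- c(labs[1:8], "...")
  cat("Leaves:", paste(labs, collapse = ", "), "\n")
  if (x$n_leaf <= 30L) cat(write_newick(x), "\n")
  invisible(x)
}

n_edges <- function(tree) {
  sum(lengths(tree$adj)) %/% 2L
}

# All edges as a 2-column matrix with u < v.
tree_edge_matrix <- function(tree) {
  N <- length(tree$adj)
  us <- rep.int(seq_len(N), lengths(tree$adj))
  vs <- unlist(tree$adj, use.names = FALSE)
  keep <- us < vs
  cbind(u = us[keep], v = vs[keep])
}

# Nodes of the component containing `start` when the edge (block, start) is
# removed.  Iterative flood fill.
nodes_beyond <- function(tree, block, start) {
  N <- length(tree$adj)
  seen <- logical(N)
  seen[c(block, start)] <- TRUE
  out <- integer(0)
  stack <- start
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, u)
    for (v in tree$adj[[u]]) {
      if (!seen[v]) {
        seen[v] <- TRUE
        stack <- c(stack, v)
      }
    }
  }
  out
}

# Taxon ranks of the leaves beyond edge (block -> start), sorted.  Served
# from the tree's split cache (one postorder pass per tree).
leafset_beyond <- function(tree, block, start) {
  ss <- splits_of(tree)
  i <- match(paste(min(block, start), max(block, start)), ss$pair_ids)
  if (is.na(i)) stop("no edge between nodes ", block, " and ", start)
  if (ss$edges[i, 2L] == start) {
    ss$vside[[i]]
  } else {
    setdiff(tree$leaves, ss$vside[[i]])
  }
}

# ---------------------------------------------------------------------------
# Canonical renumbering: leaves sorted by taxon rank become nodes 1..k,
# surviving internal nodes follow in old-id order.  `leaf_rank` holds the
# taxon rank for leaf nodes and NA for internal nodes; dead nodes (empty
# adjacency, unreferenced) are dropped.
canonical_tree <- function(taxa, leaf_rank, adj, pair_lengths = NULL,
                           binary = TRUE) {
  deg <- lengths(adj)
  alive <- which(deg > 0L | (!is.na(leaf_rank) & deg == 0L))
  is_leaf <- !is.na(leaf_rank)
  leaf_old <- alive[is_leaf[alive]]
  int_old <- alive[!is_leaf[alive]]
  leaf_old <- leaf_old[order(leaf_rank[leaf_old])]
  k <- length(leaf_old)
  newid <- integer(length(adj))
  newid[leaf_old] <- seq_len(k)
  newid[int_old] <- k + seq_along(int_old)
  adj2 <- vector("list", k + length(int_old))
  for (old in c(leaf_old, int_old)) {
    adj2[[newid[old]]] <- as.integer(newid[adj[[old]]])
  }
  tr <- new_phylo_tree(taxa, leaf_rank[leaf_old], adj2, binary = binary)
  if (!is.null(pair_lengths) && length(pair_lengths)) {
    ss <- splits_of(tr)
    el <- numeric(0)
    oldpair <- function(u2, v2) {
      ou <- c(leaf_old, int_old)[match(c(u2, v2), newid[c(leaf_old, int_old)])]
      paste(sort(ou), collapse = "|")
    }
    for (i in seq_along(ss$keys)) {
      key <- oldpair(ss$edges[i, 1L], ss$edges[i, 2L])
      if (!is.na(pair_lengths[key])) el[ss$keys[i]] <- pair_lengths[[key]]
    }
    tr$edge_lengths <- if (length(el)) el else NULL
  }
  tr
}

# ---------------------------------------------------------------------------
# Newick I/O

#' Parse a Newick string into an unrooted tree
#'
#' The text is parsed with \pkg{ape} and converted to the package's unrooted
#' representation.  A tree rooted at a bifurcation is unrooted by suppressing
#' the degree-2 root.  Edge lengths, when present, are recorded (keyed by the
#' split of their edge) and re-emitted by [write_newick()], but they play no
#' role in any topological comparison.
#'
#' @param text A single Newick statement (trailing `;` optional in `ape`).
#' @param taxa Optional [taxon_index()].  When given, the leaf labels must be
#'   a subset of it and splits are expressed in its ranks; when `NULL`, the
#'   index is the sorted leaf-label set of this tree.
#' @param allow_polytomies If `FALSE` (default) multifurcating input is
#'   rejected; if `TRUE` it is accepted, but operations that require a binary
#'   tree will fail on it.
#' @return A `phylo_tree`.
#' @examples
#' parse_newick("((a,b),(c,d));")
#' @seealso [write_newick()], [splits_of()]
#' @export
parse_newick <- function(text, taxa = NULL, allow_polytomies = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  if (!nzchar(txt)) stop("empty Newick string")
  if (length(gregexpr(";", txt, fixed = TRUE)[[1L]]) > 1L &&
      !grepl("'", txt, fixed = TRUE)) {
    stop("expected a single Newick statement")
  }

  # Shield single-quoted labels (ape keeps the quotes and trips over the
  # doubled-quote escape); restore the unescaped label afterwards.
  qlabs <- character(0)
  if (grepl("'", txt, fixed = TRUE)) {
    m <- gregexpr("'(?:[^']|'')*'", txt, perl = TRUE)[[1L]]
    if (m[1L] == -1L) stop("unbalanced quote in Newick string")
    raw <- regmatches(txt, list(m))[[1L]]
    qlabs <- gsub("''", "'", substr(raw, 2L, nchar(raw) - 1L), fixed = TRUE)
    repl <- sprintf("zzqlbl%dzz", seq_along(raw))
    regmatches(txt, list(m)) <- list(repl)
  }
  unshield <- function(labs) {
    hit <- regmatches(labs, regexec("^zzqlbl([0-9]+)zz$", labs))
    vapply(seq_along(labs), function(i) {
      if (length(hit[[i]])) qlabs[as.integer(hit[[i]][2L])] else labs[i]
    }, "")
  }

  if (!grepl("(", txt, fixed = TRUE)) {        # single-leaf tree
    lab <- unshield(sub(";\\s*$", "", txt))
    taxa <- if (is.null(taxa)) taxon_index(lab) else taxa
    return(new_phylo_tree(taxa, taxon_ranks(taxa, lab), list(integer(0))))
  }

  phy <- tryCatch(ape::read.tree(text = txt),
                  warning = function(w) stop("malformed Newick: ",
                                             conditionMessage(w)),
                  error = function(e) stop("malformed Newick: ",
                                           conditionMessage(e)))
  if (is.null(phy)) stop("malformed Newick string")
  labels <- unshield(phy$tip.label)
  if (anyNA(labels) || any(!nzchar(labels))) stop("empty leaf label")
  if (anyDuplicated(labels)) {
    stop("duplicate leaf labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (is.null(taxa)) taxa <- taxon_index(sort_labels(labels))
  ranks <- taxon_ranks(taxa, labels)

  ntip <- length(labels)
  N <- ntip + phy$Nnode
  adj <- vector("list", N)
  for (i in seq_len(N)) adj[[i]] <- integer(0)
  plen <- numeric(0)
  has_len <- !is.null(phy$edge.length)
  for (r in seq_len(nrow(phy$edge))) {
    u <- phy$edge[r, 1L]; v <- phy$edge[r, 2L]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
    if (has_len) plen[paste(sort(c(u, v)), collapse = "|")] <- phy$edge.length[r]
  }

  # Suppress degree-2 nodes (rooted input); merged edges sum their lengths.
  if (ntip >= 2L) {
    repeat {
      deg <- lengths(adj)
      d2 <- which(deg == 2L)
      d2 <- d2[d2 > ntip]
      if (!length(d2)) break
      u <- d2[1L]
      nb <- adj[[u]]
      adj[[nb[1L]]] <- c(setdiff(adj[[nb[1L]]], u), nb[2L])
      adj[[nb[2L]]] <- c(setdiff(adj[[nb[2L]]], u), nb[1L])
      adj[[u]] <- integer(0)
      if (has_len) {
        k1 <- paste(sort(c(u, nb[1L])), collapse = "|")
        k2 <- paste(sort(c(u, nb[2L])), collapse = "|")
        plen[paste(sort(nb), collapse = "|")] <-
          sum(plen[c(k1, k2)], na.rm = TRUE)
      }
    }
  }
  deg <- lengths(adj)
  if (any(deg > 3L) && !allow_polytomies) {
    stop("tree contains polytomies; set allow_polytomies = TRUE to accept ",
         "(operations requiring a binary tree will then fail)")
  }

  leaf_rank <- rep(NA_integer_, N)
  leaf_rank[seq_len(ntip)] <- ranks
  canonical_tree(taxa, leaf_rank, adj, if (has_len) plen else NULL,
                 binary = !any(deg > 3L))
}

needs_quoting <- function(lab) grepl("[][ ():,;'&]", lab)

quote_label <- function(lab) {
  ifelse(needs_quoting(lab),
         paste0("'", gsub("'", "''", lab, fixed = TRUE), "'"),
         lab)
}

#' Write a tree as a deterministic Newick string
#'
#' The output is rooted at the internal node adjacent to the tree's
#' smallest-rank leaf and children are ordered by the smallest taxon rank in
#' their subtree, so equivalent trees on the same taxon index serialize
#' identically.  Labels containing Newick metacharacters are single-quoted.
#' Edge lengths recorded by [parse_newick()] are re-emitted.
#'
#' @param tree A `phylo_tree`.
#' @return A Newick string (with trailing `;`).
#' @examples
#' write_newick(parse_newick("((b,a),(c,d));"))
#' @export
write_newick <- function(tree) {
  stopifnot(is_phylo_tree(tree))
  k <- tree$n_leaf
  labs <- quote_label(leaf_labels(tree))
  if (k == 1L) return(paste0(labs, ";"))
  if (k == 2L) return(paste0("(", labs[1L], ",", labs[2L], ");"))

  el <- tree$edge_lengths
  ss <- if (!is.null(el)) splits_of(tree) else NULL
  pairkey <- NULL
  if (!is.null(ss)) {
    pairkey <- ss$keys
    names(pairkey) <- ss$pair_ids
  }
  len_suffix <- function(u, v) {
    if (is.null(el)) return("")
    key <- pairkey[[paste(min(u, v), max(u, v))]]
    if (!is.null(key) && !is.na(el[key])) {
      paste0(":", format(el[[key]], digits = 10))
    } else ""
  }

  rec <- function(node, parent) {
    if (node <= k) {
      return(list(str = paste0(labs[node], len_suffix(node, parent)),
                  min = tree$leaves[node]))
    }
    subs <- lapply(setdiff(tree$adj[[node]], parent), rec, parent = node)
    mins <- vapply(subs, `[[`, 0L, "min")
    o <- order(mins)
    str <- paste0("(",
                  paste(vapply(subs[o], `[[`, "", "str"), collapse = ","),
                  ")")
    if (!is.na(parent)) str <- paste0(str, len_suffix(node, parent))
    list(str = str, min = min(mins))
  }
  root <- tree$adj[[1L]][1L]
  paste0(rec(root, NA_integer_)$str, ";")
}

# Convert to an ape "phylo" object (via the deterministic Newick writer).
#' Convert a phylo_tree to an ape phylo object
#' @param tree A `phylo_tree`.
#' @return An object of class `"phylo"`.
#' @export
as_ape_phylo <- function(tree) {
  ape::read.tree(text = write_newick(tree))
}
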