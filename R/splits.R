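# Splits (bipartitions) of unrooted trees, stored canonically.
#
# A split A|B is represented by one of its sides as a sorted vector of taxon
# ranks.  The canonical side is the side NOT containing the smallest-rank
# taxon present in the tree's leaf set, so A|B and B|A hash identically and
# splits are comparable across trees on the same leaf set.

canonical_side <- function(side, leaf_ranks) {
  if (leaf_ranks[1L] %in% side) {
    setdiff(leaf_ranks, side)
  } else {
    sort(unique(as.integer(side)))
  }
}

split_key <- function(side) paste(side, collapse = " ")

#' Extract the split set of a tree
#'
#' Returns one split per edge: cutting an edge bipartitions the leaf set
#' into the two subtree leaf sets.  For a binary unrooted tree with `n >= 3`
#' leaves there are `2n - 3` splits, of which `n` are trivial (one side is a
#' single leaf) and `n - 3` non-trivial.
#'
#' @param tree A `phylo_tree` with at least 2 leaves.
#' @return An object of class `"split_set"`: a list with elements `sides`
#'   (list of canonical sides as sorted taxon-rank vectors), `keys`
#'   (character identifiers, one per edge), `edges` (2-column node matrix),
#'   `trivial` (logical), `taxa` and `leaf_ranks`.
#' @examples
#' splits_of(parse_newick("((a,b),(c,d));"))
#' @export
splits_of <- function(tree) {
  stopifnot(is_phylo_tree(tree))
  cached <- tree$cache$splits
  if (!is.null(cached)) return(cached)
  if (tree$n_leaf < 2L) {
    stop("splits are defined for trees with at least 2 leaves")
  }
  k <- tree$n_leaf
  N <- length(tree$adj)
  # One postorder pass rooted next to the anchor leaf: the leaf set beyond
  # each edge's child endpoint is the union of its children's leaf sets.
  root <- tree$adj[[1L]][1L]
  parent <- rep(NA_integer_, N)
  order_seen <- integer(N)
  stack <- root
  parent[root] <- 0L
  np <- 0L
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    np <- np + 1L
    order_seen[np] <- u
    for (w in tree$adj[[u]]) {
      if (is.na(parent[w])) {
        parent[w] <- u
        stack <- c(stack, w)
      }
    }
  }
  ntaxa <- length(tree$taxa)
  below <- matrix(FALSE, nrow = N, ncol = ntaxa)
  for (i in rev(seq_len(np))) {
    u <- order_seen[i]
    if (u <= k) {
      below[u, tree$leaves[u]] <- TRUE
    }
    p <- parent[u]
    if (p > 0L) below[p, ] <- below[p, ] | below[u, ]
  }
  children <- order_seen[order_seen != root]
  vside <- lapply(children, function(v) which(below[v, ]))
  sides <- lapply(vside, canonical_side, leaf_ranks = tree$leaves)
  out <- structure(
    list(sides = sides,
         keys = vapply(sides, split_key, ""),
         edges = cbind(u = parent[children], v = children),
         vside = vside,
         pair_ids = paste(pmin(parent[children], children),
                          pmax(parent[children], children)),
         trivial = lengths(sides) %in% c(1L, k - 1L),
         taxa = tree$taxa,
         leaf_ranks = tree$leaves),
    class = "split_set")
  tree$cache$splits <- out
  out
}

#' @export
print.split_set <- function(x, ...) {
  nt <- sum(!x$trivial)
  cat("Split set:", length(x$keys), "splits (", nt, "non-trivial)\n")
  for (i in which(!x$trivial)) {
    side <- x$taxa[x$sides[[i]]]
    other <- x$taxa[setdiff(x$leaf_ranks, x$sides[[i]])]
    cat(" ", paste(side, collapse = ","), "|",
        paste(other, collapse = ","), "\n")
  }
  invisible(x)
}

nontrivial_keys <- function(tree) {
  ss <- splits_of(tree)
  ss$keys[!ss$trivial]
}

# Stable fingerprint of a tree topology; used to detect stale moves.
tree_hash <- function(tree) {
  cached <- tree$cache$hash
  if (!is.null(cached)) return(cached)
  h <- if (tree$n_leaf < 2L) {
    split_key(tree$leaves)
  } else {
    paste(split_key(tree$leaves),
          paste(sort(nontrivial_keys(tree)), collapse = ";"),
          sep = "#")
  }
  tree$cache$hash <- h
  h
}

check_same_leaves <- function(t1, t2) {
  if (!identical(t1$taxa, t2$taxa)) {
    stop("trees do not share a taxon index; parse them against the same ",
         "taxon_index() to compare them")
  }
  if (!identical(t1$leaves, t2$leaves)) stop("leaf-set mismatch between trees")
}

#' Robinson-Foulds distance between two trees
#'
#' The RF distance is the cardinality of the symmetric difference of the two
#' trees' split sets.  It is 0 exactly when the trees are topologically
#' equivalent (splits-equivalence theorem).  A single NNI always gives
#' distance 2; an SPR with path parameter `n` gives `2(n - 2)`; a TBR with
#' parameters `n, m` gives `2(n + m - 4)`.
#'
#' @param t1,t2 Trees on identical leaf sets (same taxon index).
#' @return Non-negative even integer.
#' @examples
#' rf_distance(parse_newick("((a,b),(c,d));"), parse_newick("((a,c),(b,d));"))
#' @export
rf_distance <- function(t1, t2) {
  check_same_leaves(t1, t2)
  if (t1$n_leaf < 4L) return(0L)
  k1 <- nontrivial_keys(t1)
  k2 <- nontrivial_keys(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Topological equivalence of two trees
#'
#' @inheritParams rf_distance
#' @return `TRUE` iff the RF distance is 0.  Trees with fewer than 4 leaves
#'   on the same leaf set are always equivalent (they have no non-trivial
#'   splits).
#' @export
trees_equivalent <- function(t1, t2) {
  rf_distance(t1, t2) == 0L
}

# ---------------------------------------------------------------------------
# Build a tree from a compatible set of non-trivial splits.
#
# Rooting the tree at the smallest-rank leaf (the anchor) turns each
# canonical side into a clade; compatible splits then form a laminar family
# and the tree is recovered by nesting each clade under its minimal strict
# superset.
tree_from_splits <- function(taxa, leaf_ranks, sides) {
  k <- length(leaf_ranks)
  if (k == 1L) return(new_phylo_tree(taxa, leaf_ranks, list(integer(0))))
  if (k == 2L) {
    return(new_phylo_tree(taxa, leaf_ranks, list(2L, 1L)))
  }
  sides <- sides[order(lengths(sides))]
  m <- length(sides)
  N <- k + 1L + m                       # leaves, top node, one node per clade
  top <- k + 1L
  adj <- vector("list", N)
  for (i in seq_len(N)) adj[[i]] <- integer(0)
  add_edge <- function(u, v) {
    adj[[u]] <<- c(adj[[u]], v)
    adj[[v]] <<- c(adj[[v]], u)
  }
  # membership masks over the taxon index for fast containment tests
  masks <- lapply(sides, function(s) {
    z <- logical(length(taxa)); z[s] <- TRUE; z
  })
  parent_node <- function(i) {          # minimal strict superset of clade i
    if (i < m) {
      li <- lengths(sides)[i]
      for (j in (i + 1L):m) {
        if (length(sides[[j]]) > li && all(masks[[j]][sides[[i]]])) {
          return(k + 1L + j)
        }
      }
    }
    top
  }
  for (i in seq_len(m)) add_edge(k + 1L + i, parent_node(i))
  for (t in seq_len(k)) {
    r <- leaf_ranks[t]
    p <- top
    if (t > 1L) {                       # anchor (t == 1) hangs off the top
      for (j in seq_len(m)) {
        if (masks[[j]][r]) { p <- k + 1L + j; break }
      }
    }
    add_edge(t, p)
  }
  new_phylo_tree(taxa, leaf_ranks, adj)
}

#' Restrict a tree to a taxon subset (induced partition tree)
#'
#' The induced subtree `T|Y` keeps only the leaves in `Y` and suppresses the
#' resulting degree-2 nodes.  Its split set is exactly
#' `{A intersect Y | B intersect Y : A|B a split of T, both intersections
#' non-empty}`, deduplicated; the function computes that set directly and
#' rebuilds the tree from it.  Restrictions to 1 or 2 leaves are legal
#' return values.
#'
#' @param tree A `phylo_tree`.
#' @param y Non-empty subset of the tree's leaf taxa: character labels,
#'   integer ranks, or a logical mask over the taxon index.
#' @return A `phylo_tree` with leaf set `y`.
#' @examples
#' restrict_tree(parse_newick("((a,(b,c)),(d,(e,f)));"), c("a", "b", "d", "e"))
#' @export
restrict_tree <- function(tree, y) {
  stopifnot(is_phylo_tree(tree))
  ry <- as_rank_set(tree$taxa, y)
  if (length(ry) == 0L) stop("Y must be a non-empty taxon subset")
  if (!all(ry %in% tree$leaves)) {
    stop("Y contains taxa that are not leaves of the tree: ",
         paste(tree$taxa[setdiff(ry, tree$leaves)], collapse = ", "))
  }
  kY <- length(ry)
  if (kY == tree$n_leaf) return(tree)
  sides <- list()
  if (kY >= 4L && tree$n_leaf >= 4L) {
    ss <- splits_of(tree)
    ymask <- logical(length(tree$taxa))
    ymask[ry] <- TRUE
    keep <- new.env(parent = emptyenv())
    for (i in which(!ss$trivial)) {
      s1 <- ss$sides[[i]][ymask[ss$sides[[i]]]]
      ls1 <- length(s1)
      if (ls1 < 1L || ls1 > kY - 1L) next
      side <- canonical_side(s1, ry)
      if (length(side) < 2L || length(side) > kY - 2L) next
      assign(split_key(side), side, envir = keep)
    }
    sides <- as.list(keep)
    names(sides) <- NULL
  }
  tree_from_splits(tree$taxa, ry, sides)
}

# ---------------------------------------------------------------------------
# Locate an edge by one side of its split.  Returns the oriented edge as a
# list(u, v, side): `side` (sorted ranks) is the leaf set beyond v.
find_edge <- function(tree, side) {
  ranks <- as_rank_set(tree$taxa, side)
  if (!all(ranks %in% tree$leaves)) {
    stop("split side contains taxa absent from the tree")
  }
  ss <- splits_of(tree)
  key <- split_key(canonical_side(ranks, tree$leaves))
  i <- match(key, ss$keys)
  if (is.na(i)) {
    stop("no edge with split side {",
         paste(tree$taxa[ranks], collapse = ","), "} in this tree")
  }
  v_side <- ss$vside[[i]]
  u <- ss$edges[i, 1L]; v <- ss$edges[i, 2L]
  if (identical(sort(ranks), sort(v_side))) {
    list(u = u, v = v, side = sort(ranks))
  } else {
    list(u = v, v = u, side = sort(ranks))
  }
}
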