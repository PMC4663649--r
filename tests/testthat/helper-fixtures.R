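# Shared fixtures and independent oracles.  All fixtures are built in code;
# oracles go through ape/phangorn, never through the code path they check.

# A 12-taxon tree with clearly labeled context subtrees A, B, C, D (three
# taxa each) around the central interior edge.
tree_abcd <- function() {
  parse_newick(paste0(
    "(((a1,(a2,a3)),(b1,(b2,b3))),((c1,(c2,c3)),(d1,(d2,d3))));"))
}

# 14-taxon caterpillar for SPR with n = 6: pruned subtree A = {x1,x2}, path
# subtrees B_1..B_5 single leaves b1..b5, B_6 = the 7-leaf g-subtree.
tree_spr_n6 <- function() {
  parse_newick(paste0(
    "((x1,x2),b1,(b2,(b3,(b4,(b5,",
    "(g1,(g2,(g3,(g4,(g5,(g6,g7)))))))))));"))
}

# 16-taxon tree for TBR with n = m = 4: cherries B_1..B_4 = {p,q,r,s},
# C_1..C_4 = {u,v,w,z} on the two sides of the central edge.
tree_tbr_44 <- function() {
  parse_newick(paste0(
    "(((p1,p2),((q1,q2),((r1,r2),(s1,s2)))),",
    "((u1,u2),((v1,v2),((w1,w2),(z1,z2)))));"))
}

tbr_44_move <- function(tree) {
  build_tbr_move(tree,
                 c("p1", "p2", "q1", "q2", "r1", "r2", "s1", "s2"),
                 c("s1", "s2"), c("z1", "z2"))
}

# Non-trivial split keys and the canonical key of one labeled split,
# restated from the documented canonicalization rule (side not containing
# the tree's smallest-rank leaf).
nontrivial_keys <- function(tree) {
  ss <- splits_of(tree)
  ss$keys[!ss$trivial]
}

split_key_of <- function(tree, labels) {
  ranks <- sort(match(labels, tree$taxa))
  if (tree$leaves[1L] %in% ranks) ranks <- setdiff(tree$leaves, ranks)
  paste(ranks, collapse = " ")
}

# Random valid moves, built through the public API by drawing split sides.
rand_edge_side <- function(tree) {
  ss <- splits_of(tree)
  i <- sample(length(ss$sides), 1L)
  s <- ss$sides[[i]]
  if (stats::runif(1) < 0.5) s else setdiff(ss$leaf_ranks, s)
}

random_spr_move <- function(tree) {
  repeat {
    mv <- tryCatch(
      build_spr_move(tree, rand_edge_side(tree), rand_edge_side(tree)),
      error = function(e) NULL)
    if (!is.null(mv)) return(mv)
  }
}

random_tbr_move <- function(tree) {
  ss <- splits_of(tree)
  nt <- which(!ss$trivial)
  repeat {
    mv <- tryCatch(
      build_tbr_move(tree, ss$sides[[sample(nt, 1L)]],
                     rand_edge_side(tree), rand_edge_side(tree)),
      error = function(e) NULL)
    if (!is.null(mv)) return(mv)
  }
}

random_nni_move <- function(tree) {
  mvs <- enumerate_nni_moves(tree)
  mvs[[sample(length(mvs), 1L)]]
}

# ---------------------------------------------------------------------------
# Independent oracles

oracle_rf <- function(t1, t2) {
  phangorn::RF.dist(as_ape_phylo(t1), as_ape_phylo(t2))
}

# Non-trivial splits of a tree as a canonical set of label strings,
# extracted with phangorn (independent of splits_of()).
oracle_split_labels <- function(phy) {
  sp <- phangorn::as.splits(phy)
  labs <- attr(sp, "labels")
  n <- length(labs)
  anchor <- sort(labs)[1L]
  out <- character(0)
  for (s in sp) {
    side <- labs[s]
    if (length(side) < 2L || length(side) > n - 2L) next
    if (anchor %in% side) side <- setdiff(labs, side)
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

# Canonical label strings for a package split_set (for comparison with the
# phangorn oracle).
split_labels_of <- function(tree) {
  ss <- splits_of(tree)
  labs <- leaf_labels(tree)
  anchor <- sort(labs)[1L]
  out <- vapply(ss$sides[!ss$trivial], function(s) {
    side <- tree$taxa[s]
    if (anchor %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = "|")
  }, "")
  unique(out)
}

# Did the move change the induced partition tree?  Brute-force restriction
# oracle (the slow path the predicates exist to avoid).
oracle_changed <- function(tree, moved_tree, y) {
  if (length(y) < 2L) return(FALSE)
  rf_distance(restrict_tree(tree, y), restrict_tree(moved_tree, y)) > 0L
}

# Minimum number of absent->present flips satisfying the coverage
# constraints, by exhaustive search over flip subsets (tiny grids only).
brute_min_flips <- function(m, min_taxa) {
  absent <- which(!m)
  ok <- function(mm) all(colSums(mm) >= min_taxa) && all(rowSums(mm) >= 1)
  if (ok(m)) return(0L)
  for (sz in seq_along(absent)) {
    combs <- utils::combn(absent, sz)
    for (ci in seq_len(ncol(combs))) {
      mm <- m
      mm[combs[, ci]] <- TRUE
      if (ok(mm)) return(sz)
    }
  }
  stop("unsatisfiable")
}
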