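# Partition-change predicates for NNI/SPR/TBR and induced-move mapping.
# The central check: the intersection-emptiness predicates must agree with
# the brute-force restrict-and-compare oracle on random instances.

test_that("an NNI leaves the partition tree unchanged when Y misses a subtree", {
  t <- tree_abcd()
  mv <- nni_move(t, paste0(rep(c("a", "b"), each = 3), 1:3), "AC")
  y_noA <- c(paste0("b", 1:3), paste0("c", 1:3), paste0("d", 1:3))
  rep <- nni_changes_partition(mv, y_noA, "gene1")
  expect_false(rep$changed)
  expect_equal(rep$reason, "EMPTY_INTERSECTION")
  expect_equal(rf_distance(restrict_tree(t, y_noA),
                           restrict_tree(apply_nni(t, mv), y_noA)), 0L)
  # one representative in each of A, B, C, D: changed, induced RF = 2
  y_all <- c("a1", "b2", "c3", "d1")
  rep2 <- nni_changes_partition(mv, y_all)
  expect_true(rep2$changed)
  expect_equal(rep2$reason, "CHANGED")
  expect_equal(rf_distance(restrict_tree(t, y_all),
                           restrict_tree(apply_nni(t, mv), y_all)), 2L)
})

test_that("NNI predicate equals the restriction oracle on random triples", {
  set.seed(301)
  n_changed <- 0L
  for (i in 1:300) {
    n <- sample(6:25, 1)
    t <- yule_harding_tree(n)
    mv <- random_nni_move(t)
    y <- sample(leaf_labels(t), sample(1:n, 1))
    rep <- nni_changes_partition(mv, y)
    tn <- apply_nni(t, mv)
    expect_identical(rep$changed, oracle_changed(t, tn, y))
    if (rep$changed) {
      n_changed <- n_changed + 1L
      expect_equal(rf_distance(restrict_tree(t, y), restrict_tree(tn, y)), 2L)
    }
  }
  expect_gt(n_changed, 20L)     # the sweep exercises both outcomes
})

test_that("NNI change is monotone under enlarging Y", {
  set.seed(99)
  for (i in 1:30) {
    t <- yule_harding_tree(sample(8:16, 1))
    mv <- random_nni_move(t)
    y <- t$taxa[c(mv$A[1L], mv$B[1L], mv$C[1L], mv$D[1L])]
    expect_true(nni_changes_partition(mv, y)$changed)
    rest <- setdiff(leaf_labels(t), y)
    grow <- sample(rest, min(3L, length(rest)))
    expect_true(nni_changes_partition(mv, c(y, grow))$changed)
  }
})

test_that("SPR predicate fires iff A and three path subtrees are represented", {
  t <- tree_spr_n6()
  mv <- build_spr_move(t, c("x1", "x2"), paste0("g", 1:7))
  ts <- apply_spr(t, mv)
  # A unrepresented: every changed split restricts to a shared one
  y <- c("b1", "b2", "b3", "g1", "g2")
  rep <- spr_changes_partition(mv, y)
  expect_false(rep$changed)
  expect_equal(rep$reason, "EMPTY_INTERSECTION")
  expect_false(oracle_changed(t, ts, y))
  # A plus exactly two path subtrees: still no quartet structure
  y2 <- c("x1", "b2", "g3")
  rep2 <- spr_changes_partition(mv, y2)
  expect_false(rep2$changed)
  expect_false(oracle_changed(t, ts, y2))
  # A plus exactly three path subtrees: changed with induced RF 2
  y3 <- c("x1", "b2", "b4", "g1", "g5")
  rep3 <- spr_changes_partition(mv, y3)
  expect_true(rep3$changed)
  expect_equal(rf_distance(restrict_tree(t, y3), restrict_tree(ts, y3)), 2L)
  # ... and the induced move is an NNI (a 3-SPR) on the partition tree
  expect_equal(rep3$induced_move$n_induced, 3L)
})

test_that("A-plus-two-B configurations report NO_QUARTET", {
  t <- tree_spr_n6()
  mv <- build_spr_move(t, c("x1", "x2"), paste0("g", 1:7))
  rep <- spr_changes_partition(mv, c("x1", "x2", "b1", "b5"))
  expect_false(rep$changed)
  expect_equal(rep$reason, "NO_QUARTET")
  rep2 <- spr_changes_partition(mv, c("x1", "b1"))
  expect_equal(rep2$reason, "TOO_FEW_TAXA")
})

test_that("SPR predicate and induced move agree with the oracle", {
  set.seed(302)
  n_changed <- 0L
  for (i in 1:200) {
    n <- sample(6:25, 1)
    t <- yule_harding_tree(n)
    mv <- random_spr_move(t)
    y <- sample(leaf_labels(t), sample(1:n, 1))
    rep <- spr_changes_partition(mv, y)
    ts <- apply_spr(t, mv)
    expect_identical(rep$changed, oracle_changed(t, ts, y))
    if (rep$changed) {
      n_changed <- n_changed + 1L
      replayed <- apply_induced_move(restrict_tree(t, y), rep$induced_move)
      expect_equal(rf_distance(replayed, restrict_tree(ts, y)), 0L)
    }
  }
  expect_gt(n_changed, 20L)
})

test_that("with full coverage the induced SPR echoes the original move", {
  t <- tree_spr_n6()
  mv <- build_spr_move(t, c("x1", "x2"), paste0("g", 1:7))
  im <- induced_spr_move(mv, leaf_labels(t))
  expect_equal(sort(t$taxa[im$prune_side]), c("x1", "x2"))
  expect_equal(sort(t$taxa[im$regraft_side]), paste0("g", 1:7))
  expect_equal(im$n_induced, mv$n)
  # calling the induced-move constructor on an unchanged partition errors
  expect_error(induced_spr_move(mv, c("b1", "b2", "b3", "b4")),
               "does not change")
})

test_that("TBR two-plus-two configurations are unchanged, one-plus-three changed", {
  t <- tree_tbr_44()
  mv <- tbr_44_move(t)
  tb <- apply_tbr(t, mv)
  # two represented subtrees on each side: RF 0
  y22 <- c("p1", "q1", "u1", "v1")
  rep <- tbr_changes_partition(mv, y22)
  expect_false(rep$changed)
  expect_equal(rep$reason, "NO_QUARTET")
  expect_equal(rf_distance(restrict_tree(t, y22), restrict_tree(tb, y22)), 0L)
  # one B plus three C: RF 2, induced move is an NNI on the partition tree
  y13 <- c("p1", "u1", "v1", "w1")
  rep2 <- tbr_changes_partition(mv, y13)
  expect_true(rep2$changed)
  expect_equal(rf_distance(restrict_tree(t, y13), restrict_tree(tb, y13)), 2L)
  expect_equal(rep2$induced_move$n_induced, 1L)
  expect_equal(rep2$induced_move$m_induced, 3L)
  # a side with no representative: unchanged
  yB0 <- c("u1", "v1", "w1", "z1")
  rep3 <- tbr_changes_partition(mv, yB0)
  expect_false(rep3$changed)
  expect_equal(rep3$reason, "EMPTY_INTERSECTION")
  expect_false(oracle_changed(t, tb, yB0))
})

test_that("TBR predicate and induced move agree with the oracle", {
  set.seed(303)
  n_changed <- 0L
  for (i in 1:200) {
    n <- sample(8:25, 1)
    t <- yule_harding_tree(n)
    mv <- random_tbr_move(t)
    y <- sample(leaf_labels(t), sample(1:n, 1))
    rep <- tbr_changes_partition(mv, y)
    tb <- apply_tbr(t, mv)
    expect_identical(rep$changed, oracle_changed(t, tb, y))
    if (rep$changed) {
      n_changed <- n_changed + 1L
      replayed <- apply_induced_move(restrict_tree(t, y), rep$induced_move)
      expect_equal(rf_distance(replayed, restrict_tree(tb, y)), 0L)
    }
  }
  expect_gt(n_changed, 20L)
})

test_that("partitions with at most three taxa never change", {
  set.seed(304)
  for (i in 1:40) {
    t <- yule_harding_tree(sample(8:18, 1))
    y <- sample(leaf_labels(t), sample(1:3, 1))
    expect_false(nni_changes_partition(random_nni_move(t), y)$changed)
    expect_false(spr_changes_partition(random_spr_move(t), y)$changed)
    expect_false(tbr_changes_partition(random_tbr_move(t), y)$changed)
  }
})

test_that("reports carry machine-readable structure", {
  t <- tree_abcd()
  mv <- nni_move(t, paste0(rep(c("a", "b"), each = 3), 1:3), "AC")
  rep <- nni_changes_partition(mv, c("a1", "b1", "c1", "d1"), "p7")
  expect_s3_class(rep, "partition_change_report")
  expect_equal(rep$partition_id, "p7")
  expect_null(rep$induced_move)     # NNI reports never carry induced moves
  smv <- build_spr_move(tree_spr_n6(), c("x1", "x2"), paste0("g", 1:7))
  srep <- spr_changes_partition(smv, c("x1", "b1", "b3", "g2"))
  expect_true(srep$changed)
  expect_s3_class(srep$induced_move, "induced_move")
})

test_that("edge relevance for a partition follows split-side intersections", {
  t <- tree_abcd()
  y <- c(paste0("b", 1:3), "c1")
  # trivial split of a taxon outside Y: edge cannot affect the partition
  expect_false(edge_affects_partition(t, "a1", y))
  # split with Y members on both sides
  expect_true(edge_affects_partition(t, paste0("b", 1:3), y))
  # restriction oracle: exactly the affecting edges project onto the split
  # set of T|Y; irrelevant edges contribute nothing
  set.seed(305)
  for (i in 1:20) {
    tr <- yule_harding_tree(10)
    yy <- sample(leaf_labels(tr), sample(4:8, 1))
    ry <- restrict_tree(tr, yy)
    ss <- splits_of(tr)
    projected <- character(0)
    for (j in seq_along(ss$sides)) {
      side <- tr$taxa[ss$sides[[j]]]
      affects <- edge_affects_partition(tr, side, yy)
      proj <- intersect(side, yy)
      # an edge affects the partition iff its split survives restriction
      expect_identical(affects,
                       length(proj) > 0L && length(proj) < length(yy))
      if (affects && length(proj) >= 2L && length(proj) <= length(yy) - 2L) {
        projected <- c(projected, split_key_of(ry, proj))
      }
    }
    expect_setequal(unique(projected), nontrivial_keys(ry))
  }
})
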