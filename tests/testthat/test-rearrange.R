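# NNI, SPR and TBR moves: enumeration, context resolution, application,
# predicted changed splits and RF formulas.

test_that("NNI neighborhood has size 2(n-3) with pairwise distinct topologies", {
  expect_length(enumerate_nni_moves(parse_newick("((a,b),(c,d));")), 2L)
  expect_length(enumerate_nni_moves(parse_newick("(a,b,c);")), 0L)
  t10 <- yule_harding_tree(10, seed = 5)
  mvs <- enumerate_nni_moves(t10)
  expect_length(mvs, 14L)
  nbs <- lapply(mvs, apply_nni, tree = t10)
  for (i in seq_along(nbs)) {
    expect_equal(rf_distance(t10, nbs[[i]]), 2L)
  }
  # caterpillar: all neighbors pairwise distinct
  cat8 <- parse_newick("(a,(b,(c,(d,(e,(f,(g,h)))))));")
  nb <- lapply(enumerate_nni_moves(cat8), apply_nni, tree = cat8)
  for (i in seq_along(nb)) {
    for (j in seq_len(i - 1L)) {
      expect_gt(rf_distance(nb[[i]], nb[[j]]), 0L)
    }
  }
})

test_that("NNI context resolution gives the quartet around the edge", {
  q <- parse_newick("((a,b),(c,d));")
  ctx <- resolve_nni_context(q, c("a", "b"))
  expect_equal(lapply(ctx[c("A", "B", "C", "D")], function(s) q$taxa[s]),
               list(A = "a", B = "b", C = "c", D = "d"))
  t <- tree_abcd()
  ctx <- resolve_nni_context(t, paste0(rep(c("a", "b"), each = 3), 1:3))
  expect_equal(sort(t$taxa[ctx$A]), c("a1", "a2", "a3"))
  expect_equal(sort(t$taxa[ctx$B]), c("b1", "b2", "b3"))
  expect_equal(sort(t$taxa[ctx$C]), c("c1", "c2", "c3"))
  expect_equal(sort(t$taxa[ctx$D]), c("d1", "d2", "d3"))
  # context sets partition the taxon set
  set.seed(3)
  tr <- yule_harding_tree(12)
  for (mv in enumerate_nni_moves(tr)) {
    expect_setequal(c(mv$A, mv$B, mv$C, mv$D), tr$leaves)
    expect_equal(sum(lengths(mv[c("A", "B", "C", "D")])), 12L)
  }
  expect_error(resolve_nni_context(q, "a"), "not interior")
})

test_that("NNI application changes exactly the two predicted splits", {
  q <- parse_newick("((a,b),(c,d));")
  got <- sort(vapply(enumerate_nni_moves(q),
                     function(m) write_newick(apply_nni(q, m)), ""))
  expect_setequal(got, c(write_newick(parse_newick("((a,c),(b,d));",
                                                   taxa = taxon_index(q$taxa))),
                         write_newick(parse_newick("((a,d),(b,c));",
                                                   taxa = taxon_index(q$taxa)))))
  set.seed(21)
  for (i in 1:25) {
    t <- yule_harding_tree(sample(5:18, 1))
    for (mv in enumerate_nni_moves(t)) {
      tn <- apply_nni(t, mv)
      sym <- union(setdiff(nontrivial_keys(t), nontrivial_keys(tn)),
                   setdiff(nontrivial_keys(tn), nontrivial_keys(t)))
      expect_setequal(sym, predicted_changed_splits(mv))
      expect_equal(rf_distance(t, tn), 2L)
    }
  }
})

test_that("the same NNI applied twice is an involution and input is unchanged", {
  set.seed(8)
  t <- yule_harding_tree(12)
  before <- write_newick(t)
  mv <- random_nni_move(t)
  t2 <- apply_nni(t, mv)
  expect_identical(write_newick(t), before)
  # the rearranged central edge now carries the predicted new split; one of
  # the two NNIs on it restores the original topology
  new_edge <- if (mv$exchange == "AC") c(mv$A, mv$D) else c(mv$A, mv$C)
  t3 <- apply_nni(t2, nni_move(t2, t$taxa[new_edge], "AC"))
  t4 <- apply_nni(t2, nni_move(t2, t$taxa[new_edge], "AD"))
  expect_true(trees_equivalent(t, t3) || trees_equivalent(t, t4))
})

test_that("stale moves are rejected", {
  t <- yule_harding_tree(8, seed = 2)
  mv <- random_nni_move(t)
  t2 <- apply_nni(t, mv)
  expect_error(apply_nni(t2, mv), "stale")
  ms <- random_spr_move(t)
  expect_error(apply_spr(t2, ms), "stale")
})

test_that("SPR path decomposition follows the attachment-to-regraft walk", {
  t <- tree_spr_n6()
  mv <- build_spr_move(t, c("x1", "x2"), paste0("g", 1:7))
  expect_equal(mv$n, 6L)
  expect_false(mv$nni_equivalent)
  expect_equal(sort(t$taxa[mv$A]), c("x1", "x2"))
  for (i in 1:5) expect_equal(t$taxa[mv$B[[i]]], paste0("b", i))
  expect_equal(sort(t$taxa[mv$B[[6]]]), paste0("g", 1:7))
  # identity and containment errors
  expect_error(build_spr_move(t, c("x1", "x2"), "b1"),
               "incident to the attachment")
  expect_error(build_spr_move(t, paste0("g", 1:7), "g1"),
               "pruned subtree")
})

test_that("a 3-SPR is an NNI", {
  t <- yule_harding_tree(9, seed = 13)
  set.seed(13)
  repeat {
    mv <- random_spr_move(t)
    if (mv$n == 3L) break
  }
  expect_true(mv$nni_equivalent)
  ts <- apply_spr(t, mv)
  expect_equal(rf_distance(t, ts), 2L)
  nni_results <- lapply(enumerate_nni_moves(t), apply_nni, tree = t)
  expect_true(any(vapply(nni_results, trees_equivalent, NA, t1 = ts)))
})

test_that("SPR changes exactly the path-edge splits and is reversible", {
  t <- tree_spr_n6()
  mv <- build_spr_move(t, c("x1", "x2"), paste0("g", 1:7))
  ts <- apply_spr(t, mv)
  expect_equal(rf_distance(t, ts), 2L * (mv$n - 2L))
  sym <- union(setdiff(nontrivial_keys(t), nontrivial_keys(ts)),
               setdiff(nontrivial_keys(ts), nontrivial_keys(t)))
  expect_setequal(sym, predicted_changed_splits(mv))
  # regrafting A back onto the merged B_1 edge restores the topology
  back <- build_spr_move(ts, t$taxa[mv$A], t$taxa[mv$B[[1L]]])
  expect_true(trees_equivalent(apply_spr(ts, back), t))
})

test_that("TBR preserves the bisection split and honors its constraints", {
  t <- tree_tbr_44()
  mv <- tbr_44_move(t)
  expect_equal(c(mv$n, mv$m), c(4L, 4L))
  tb <- apply_tbr(t, mv)
  bkey <- split_key_of(t, paste0(rep(c("p", "q", "r", "s"), each = 2), 1:2))
  expect_true(bkey %in% nontrivial_keys(tb))
  expect_equal(rf_distance(t, tb), 2L * (4L + 4L - 4L))
  sym <- union(setdiff(nontrivial_keys(t), nontrivial_keys(tb)),
               setdiff(nontrivial_keys(tb), nontrivial_keys(t)))
  expect_setequal(sym, predicted_changed_splits(mv))
  # identity: both reconnect edges adjacent to the bisection
  expect_error(build_tbr_move(t, c("p1", "p2", "q1", "q2", "r1", "r2",
                                   "s1", "s2"),
                              c("p1", "p2", "q1", "q2", "r1", "r2",
                                "s1", "s2"),
                              c("u1", "u2", "v1", "v2", "w1", "w2",
                                "z1", "z2")),
               "coincides|identity")
  # reconnect edges must sit in different components
  expect_error(build_tbr_move(t, c("p1", "p2", "q1", "q2", "r1", "r2",
                                   "s1", "s2"),
                              c("s1", "s2"), c("r1", "r2")),
               "different components")
})

test_that("degenerate TBRs are flagged NNI- or SPR-equivalent", {
  t <- tree_tbr_44()
  bis <- c("p1", "p2", "q1", "q2", "r1", "r2", "s1", "s2")
  m_nni <- build_tbr_move(t, bis, c("q1", "q2", "r1", "r2", "s1", "s2"),
                          c("v1", "v2"))
  expect_equal(sort(c(m_nni$n, m_nni$m)), c(2L, 3L))
  expect_equal(m_nni$equivalent, "NNI")
  m_spr <- build_tbr_move(t, bis, c("s1", "s2"), c("u1", "u2"))
  expect_equal(sort(c(m_spr$n, m_spr$m)), c(2L, 4L))
  expect_equal(m_spr$equivalent, "SPR")
  # the m = 2 TBR equals the corresponding SPR application
  tb <- apply_tbr(t, m_spr)
  spr <- build_spr_move(t, c("u1", "u2", "v1", "v2", "w1", "w2", "z1", "z2"),
                        c("s1", "s2"))
  expect_true(trees_equivalent(tb, apply_spr(t, spr)))
})

test_that("predicted RF equals computed RF on 200 random SPR/TBR moves", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    t <- yule_harding_tree(n)
    ms <- random_spr_move(t)
    expect_equal(predicted_rf(ms), rf_distance(t, apply_spr(t, ms)))
    if (n >= 8) {
      mt <- random_tbr_move(t)
      expect_equal(predicted_rf(mt), rf_distance(t, apply_tbr(t, mt)))
    }
  }
  expect_equal(predicted_rf(random_nni_move(yule_harding_tree(10, seed = 1))),
               2L)
})

test_that("radius-capped SPR/TBR enumeration yields valid, bounded moves", {
  t <- yule_harding_tree(8, seed = 31)
  sprs <- enumerate_spr_moves(t, radius = 4)
  expect_gt(length(sprs), 0L)
  for (mv in sprs) {
    expect_lte(mv$n, 4L)
    expect_gte(mv$n, 3L)
    expect_equal(rf_distance(t, apply_spr(t, mv)), predicted_rf(mv))
  }
  tbrs <- enumerate_tbr_moves(t, radius = 3)
  expect_gt(length(tbrs), 0L)
  for (mv in tbrs) {
    expect_lte(max(mv$n, mv$m), 3L)
    expect_equal(rf_distance(t, apply_tbr(t, mv)), predicted_rf(mv))
  }
})

test_that("moves serialize to split-identified records", {
  t <- tree_spr_n6()
  mv <- build_spr_move(t, c("x1", "x2"), paste0("g", 1:7))
  rec <- move_to_record(mv)
  expect_equal(rec$kind, "SPR")
  expect_equal(rec$prune, c("x1", "x2"))
  expect_equal(rec$n, 6L)
  rec2 <- move_to_record(random_nni_move(yule_harding_tree(8, seed = 4)))
  expect_true(all(c("kind", "edge", "exchange") %in% names(rec2)))
})
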