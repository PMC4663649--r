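# Fast predicates deciding whether a rearrangement of the species tree
# changes the topology of an induced partition tree, and the mapping of a
# species-tree move to the induced move on the partition tree.
#
# The predicates work purely on emptiness tests of intersections between the
# move's context taxon sets and the partition's taxon set Y; no restricted
# tree is ever built.  The restricted-tree route (restrict + RF) exists only
# as the testing oracle.

reason_codes <- c("CHANGED", "TOO_FEW_TAXA", "EMPTY_INTERSECTION",
                  "NO_QUARTET")

new_change_report <- function(partition_id, changed, reason,
                              induced_move = NULL) {
  structure(list(partition_id = partition_id,
                 changed = changed,
                 reason = reason,
                 induced_move = induced_move),
            class = "partition_change_report")
}

#' @export
print.partition_change_report <- function(x, ...) {
  cat("Partition", x$partition_id %||% "<unnamed>", ":",
      if (x$changed) "CHANGED" else "unchanged",
      paste0("(", x$reason, ")"), "\n")
  if (!is.null(x$induced_move)) print(x$induced_move)
  invisible(x)
}

# Y as a logical mask over the move's taxon index.
y_mask <- function(move, y) {
  if (is.logical(y) && length(y) == length(move$taxa)) {
    if (!any(y)) stop("Y must be non-empty")
    return(y)
  }
  ry <- as_rank_set(move$taxa, y)
  if (length(ry) == 0L) stop("Y must be non-empty")
  mask <- logical(length(move$taxa))
  mask[ry] <- TRUE
  mask
}

n_in_tree <- function(move, mask) sum(mask[move$leaf_ranks])

#' Does an NNI change the induced partition tree?
#'
#' The topologies of `T|Y` and `T_NNI|Y` differ exactly when `Y` has at
#' least one representative taxon in each of the four context subtrees `A`,
#' `B`, `C`, `D` around the NNI edge; otherwise the two changed splits
#' restrict to splits shared by both induced trees and the RF distance
#' between them is 0.
#'
#' @param move An `nni_move`.
#' @param y The partition's taxon set (labels, ranks or mask).
#' @param partition_id Optional identifier echoed in the report.
#' @return A `partition_change_report`.
#' @export
nni_changes_partition <- function(move, y, partition_id = NULL) {
  stopifnot(inherits(move, "nni_move"))
  mask <- y_mask(move, y)
  hit <- c(any(mask[move$A]), any(mask[move$B]),
           any(mask[move$C]), any(mask[move$D]))
  if (all(hit)) {
    new_change_report(partition_id, TRUE, "CHANGED")
  } else if (n_in_tree(move, mask) <= 3L) {
    new_change_report(partition_id, FALSE, "TOO_FEW_TAXA")
  } else {
    new_change_report(partition_id, FALSE, "EMPTY_INTERSECTION")
  }
}

#' Does an SPR change the induced partition tree?
#'
#' The topologies of `T|Y` and `T_SPR|Y` differ exactly when `Y` has a
#' representative in the pruned subtree `A` and in at least three of the
#' path subtrees `B_1, ..., B_n` (the induced tree then has the quartet
#' structure required for at least an NNI).  When changed, the induced-move
#' descriptor (see [induced_spr_move()]) is attached to the report.
#'
#' @param move An `spr_move`.
#' @inheritParams nni_changes_partition
#' @return A `partition_change_report` (with `induced_move` when changed).
#' @export
spr_changes_partition <- function(move, y, partition_id = NULL) {
  stopifnot(inherits(move, "spr_move"))
  mask <- y_mask(move, y)
  repA <- any(mask[move$A])
  hitB <- vapply(move$B, function(s) any(mask[s]), NA)
  if (repA && sum(hitB) >= 3L) {
    new_change_report(partition_id, TRUE, "CHANGED",
                      induced_move = induced_spr_move(move, y))
  } else if (n_in_tree(move, mask) <= 3L) {
    new_change_report(partition_id, FALSE, "TOO_FEW_TAXA")
  } else if (!repA) {
    new_change_report(partition_id, FALSE, "EMPTY_INTERSECTION")
  } else {
    new_change_report(partition_id, FALSE, "NO_QUARTET")
  }
}

#' Does a TBR change the induced partition tree?
#'
#' The topologies of `T|Y` and `T_TBR|Y` differ exactly when `Y` represents
#' at least one subtree on one side of the bisection and at least three on
#' the other side.  The two-per-side configuration leaves the induced tree
#' unchanged (the restricted splits coincide pairwise), as does any
#' configuration with an unrepresented side.
#'
#' @param move A `tbr_move`.
#' @inheritParams nni_changes_partition
#' @return A `partition_change_report` (with `induced_move` when changed).
#' @export
tbr_changes_partition <- function(move, y, partition_id = NULL) {
  stopifnot(inherits(move, "tbr_move"))
  mask <- y_mask(move, y)
  nB <- sum(vapply(move$B, function(s) any(mask[s]), NA))
  nC <- sum(vapply(move$C, function(s) any(mask[s]), NA))
  if ((nB >= 1L && nC >= 3L) || (nB >= 3L && nC >= 1L)) {
    new_change_report(partition_id, TRUE, "CHANGED",
                      induced_move = induced_tbr_move(move, y))
  } else if (n_in_tree(move, mask) <= 3L) {
    new_change_report(partition_id, FALSE, "TOO_FEW_TAXA")
  } else if (nB == 0L || nC == 0L) {
    new_change_report(partition_id, FALSE, "EMPTY_INTERSECTION")
  } else {
    new_change_report(partition_id, FALSE, "NO_QUARTET")
  }
}

#' Generic change predicate for any move kind
#' @param move An `nni_move`, `spr_move` or `tbr_move`.
#' @inheritParams nni_changes_partition
#' @return A `partition_change_report`.
#' @export
move_changes_partition <- function(move, y, partition_id = NULL) {
  switch(move$kind,
         NNI = nni_changes_partition(move, y, partition_id),
         SPR = spr_changes_partition(move, y, partition_id),
         TBR = tbr_changes_partition(move, y, partition_id),
         stop("unknown move kind"))
}

# ---------------------------------------------------------------------------
# Induced moves

new_induced_move <- function(kind, taxa, fields) {
  structure(c(list(kind = kind, taxa = taxa), fields),
            class = "induced_move")
}

#' @export
print.induced_move <- function(x, ...) {
  show <- function(s) paste(sort_labels(x$taxa[s]), collapse = ",")
  if (x$kind == "SPR") {
    cat("Induced SPR on T|Y: prune {", show(x$prune_side), "} | {",
        show(x$prune_other), "}, regraft onto {", show(x$regraft_side),
        "} | {", show(x$regraft_other), "}",
        if (x$n_induced == 3L) " (an NNI on T|Y)", "\n", sep = "")
  } else {
    cat("Induced TBR on T|Y: cut {", show(x$cut_b), "} | {", show(x$cut_c),
        "}, reconnect {", show(x$reconnect_b_side), "} and {",
        show(x$reconnect_c_side), "}\n", sep = "")
  }
  invisible(x)
}

#' Induced SPR move on the partition tree
#'
#' When an SPR changes `T|Y`, it corresponds to an SPR on `T|Y` that prunes
#' the subtree below the edge with split `A&Y | (B_1+...+B_n)&Y` and
#' regrafts it onto the edge with split `B_k&Y | rest`, where
#' `k = max { i : B_i & Y != empty }`.  Its path parameter equals the number
#' of represented path subtrees, so a long SPR on the species tree may be a
#' short SPR (or an NNI) on the partition tree.
#'
#' @param move An `spr_move` for which [spr_changes_partition()] is changed.
#' @param y The partition's taxon set.
#' @return An `induced_move` descriptor.
#' @export
induced_spr_move <- function(move, y) {
  stopifnot(inherits(move, "spr_move"))
  mask <- y_mask(move, y)
  repA <- any(mask[move$A])
  hitB <- vapply(move$B, function(s) any(mask[s]), NA)
  if (!repA || sum(hitB) < 3L) {
    stop("the SPR does not change this partition tree; no induced move")
  }
  kk <- max(which(hitB))
  cut <- function(s) sort(s[mask[s]])
  allB <- sort(unlist(move$B))
  new_induced_move("SPR", move$taxa, list(
    prune_side = cut(move$A),
    prune_other = cut(allB),
    regraft_side = cut(move$B[[kk]]),
    regraft_other = cut(c(move$A, unlist(move$B[-kk]))),
    k = kk,
    n_induced = as.integer(sum(hitB))))
}

#' Induced TBR move on the partition tree
#'
#' When a TBR changes `T|Y`, it corresponds to a TBR on `T|Y` that cuts the
#' edge with split `(B_1+...+B_n)&Y | (C_1+...+C_m)&Y` and reconnects the
#' edges with splits `B_k&Y | rest` and `C_h&Y | rest`, where `k` and `h`
#' are the largest represented indices on each side.  When only one subtree
#' on a side is represented the reconnect split on that side coincides with
#' the cut split and the induced move degenerates to an SPR on `T|Y`
#' (handled by [apply_induced_move()]).
#'
#' @param move A `tbr_move` for which [tbr_changes_partition()] is changed.
#' @param y The partition's taxon set.
#' @return An `induced_move` descriptor.
#' @export
induced_tbr_move <- function(move, y) {
  stopifnot(inherits(move, "tbr_move"))
  mask <- y_mask(move, y)
  hitB <- vapply(move$B, function(s) any(mask[s]), NA)
  hitC <- vapply(move$C, function(s) any(mask[s]), NA)
  nB <- sum(hitB); nC <- sum(hitC)
  if (!((nB >= 1L && nC >= 3L) || (nB >= 3L && nC >= 1L))) {
    stop("the TBR does not change this partition tree; no induced move")
  }
  kk <- max(which(hitB)); hh <- max(which(hitC))
  cut <- function(s) sort(s[mask[s]])
  allB <- sort(unlist(move$B)); allC <- sort(unlist(move$C))
  new_induced_move("TBR", move$taxa, list(
    cut_b = cut(allB),
    cut_c = cut(allC),
    reconnect_b_side = cut(move$B[[kk]]),
    reconnect_b_other = cut(c(unlist(move$B[-kk]), allC)),
    reconnect_c_side = cut(move$C[[hh]]),
    reconnect_c_other = cut(c(unlist(move$C[-hh]), allB)),
    k = kk, h = hh,
    n_induced = as.integer(nB), m_induced = as.integer(nC)))
}

#' Apply an induced move to a partition tree
#'
#' Replays the induced-move descriptor on the restricted tree `T|Y`; the
#' result is topologically equivalent to `T_move|Y`.  Degenerate induced
#' TBRs (one represented subtree on a side) are applied as the
#' corresponding SPR.
#'
#' @param tree_y The restricted tree `restrict_tree(tree, y)`.
#' @param im An `induced_move`.
#' @return A `phylo_tree`.
#' @export
apply_induced_move <- function(tree_y, im) {
  stopifnot(inherits(im, "induced_move"))
  if (im$kind == "SPR") {
    mv <- build_spr_move(tree_y, im$prune_side, im$regraft_side)
    return(apply_spr(tree_y, mv))
  }
  if (im$n_induced == 1L) {            # B side collapses: SPR pruning it
    mv <- build_spr_move(tree_y, im$cut_b, im$reconnect_c_side)
    return(apply_spr(tree_y, mv))
  }
  if (im$m_induced == 1L) {            # C side collapses
    mv <- build_spr_move(tree_y, im$cut_c, im$reconnect_b_side)
    return(apply_spr(tree_y, mv))
  }
  mv <- build_tbr_move(tree_y, im$cut_b, im$reconnect_b_side,
                       im$reconnect_c_side)
  apply_tbr(tree_y, mv)
}

# ---------------------------------------------------------------------------

#' Does optimizing an edge affect a partition's likelihood?
#'
#' An edge with split `A|B` has no counterpart in the induced partition tree
#' `T|Y` when `A & Y` or `B & Y` is empty; under an edge-linked partition
#' model, optimizing the length of such an edge cannot affect the
#' partition's likelihood, so the computation can be skipped.
#'
#' @param tree A `phylo_tree`.
#' @param edge One side of the edge's split (labels, ranks or mask).
#' @param y The partition's taxon set.
#' @return `TRUE` iff both sides of the split intersect `y`.
#' @export
edge_affects_partition <- function(tree, edge, y) {
  ranks <- as_rank_set(tree$taxa, edge)
  ry <- as_rank_set(tree$taxa, y)
  other <- setdiff(tree$leaves, ranks)
  any(ry %in% ranks) && any(ry %in% other)
}
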