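# NNI, SPR and TBR rearrangements with resolved context subtrees.
#
# A move is a value object bound to a specific tree snapshot (its topology
# hash); applying it to a structurally different tree is an error.  Context
# subtree taxon sets (A,B,C,D for NNI; A,B_1..B_n for SPR; B_1..B_n,C_1..C_m
# for TBR) are resolved at build time, because the partial-terrace predicates
# operate on those sets alone.

check_binary <- function(tree) {
  if (isTRUE(attr(tree, "polytomies"))) {
    stop("operation requires a bifurcating (binary) tree")
  }
  invisible(tree)
}

new_move <- function(kind, tree, fields) {
  structure(c(list(kind = kind,
                   taxa = tree$taxa,
                   leaf_ranks = tree$leaves,
                   hash = tree_hash(tree)),
              fields),
            class = c(paste0(tolower(kind), "_move"), "phylo_move"))
}

check_move <- function(tree, move) {
  stopifnot(inherits(move, "phylo_move"))
  if (!identical(move$hash, tree_hash(tree))) {
    stop("stale move: it was built on a different tree topology")
  }
}

#' @export
print.phylo_move <- function(x, ...) {
  lab <- function(s) paste(x$taxa[s], collapse = ",")
  cat(x$kind, "move\n")
  if (x$kind == "NNI") {
    cat("  edge:", x$edge_key_labels, " exchange:", x$exchange, "\n")
    cat("  A={", lab(x$A), "} B={", lab(x$B), "} C={", lab(x$C),
        "} D={", lab(x$D), "}\n", sep = "")
  } else if (x$kind == "SPR") {
    cat("  prune A={", lab(x$A), "}, regraft beyond B_", x$n,
        ", path parameter n=", x$n,
        if (isTRUE(x$nni_equivalent)) " (NNI-equivalent)", "\n", sep = "")
  } else {
    cat("  bisection n=", x$n, " m=", x$m,
        if (!is.null(x$equivalent)) paste0(" (", x$equivalent, "-equivalent)"),
        "\n", sep = "")
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# NNI

#' Resolve the quartet context around an interior edge
#'
#' An interior edge `e` has four incident edges whose subtrees carry taxon
#' sets `A`, `B`, `C`, `D`.  Convention: `A` and `B` hang off the endpoint
#' whose component contains the tree's smallest-rank leaf, `C` and `D` off
#' the other endpoint; within an endpoint the set containing the smaller
#' minimum rank comes first (`A` before `B`, `C` before `D`).
#'
#' @param tree A binary `phylo_tree` with at least 4 leaves.
#' @param edge One side of the edge's split (labels, ranks or mask).
#' @return A list with taxon-rank sets `A`, `B`, `C`, `D` and the internal
#'   node bookkeeping used by [apply_nni()].
#' @export
resolve_nni_context <- function(tree, edge) {
  check_binary(tree)
  fe <- find_edge(tree, edge)
  resolve_nni_context_nodes(tree, fe$u, fe$v)
}

resolve_nni_context_nodes <- function(tree, u, v) {
  k <- tree$n_leaf
  if (u <= k || v <= k) stop("edge is not interior")
  # host endpoint = the one on the anchor-leaf side of the edge
  anchor_side_u <- !(tree$leaves[1L] %in% leafset_beyond(tree, u, v))
  if (!anchor_side_u) { tmp <- u; u <- v; v <- tmp }
  nb_u <- setdiff(tree$adj[[u]], v)
  nb_v <- setdiff(tree$adj[[v]], u)
  S_u <- lapply(nb_u, function(w) leafset_beyond(tree, u, w))
  S_v <- lapply(nb_v, function(w) leafset_beyond(tree, v, w))
  ou <- order(vapply(S_u, min, 0L))
  ov <- order(vapply(S_v, min, 0L))
  list(u = u, v = v,
       a_node = nb_u[ou[1L]], b_node = nb_u[ou[2L]],
       c_node = nb_v[ov[1L]], d_node = nb_v[ov[2L]],
       A = S_u[[ou[1L]]], B = S_u[[ou[2L]]],
       C = S_v[[ov[1L]]], D = S_v[[ov[2L]]])
}

#' Construct an NNI move
#'
#' For each interior edge there are two NNIs: exchanging subtree `A` with
#' `C` (`exchange = "AC"`) or `A` with `D` (`"AD"`), in the context-set
#' convention of [resolve_nni_context()].
#'
#' @inheritParams resolve_nni_context
#' @param exchange `"AC"` or `"AD"`.
#' @return An object of class `nni_move`.
#' @export
nni_move <- function(tree, edge, exchange = c("AC", "AD")) {
  exchange <- match.arg(exchange)
  ctx <- resolve_nni_context(tree, edge)
  nni_move_from_context(tree, ctx, exchange)
}

nni_move_from_context <- function(tree, ctx, exchange) {
  side <- canonical_side(sort(c(ctx$A, ctx$B)), tree$leaves)
  new_move("NNI", tree,
           c(ctx, list(exchange = exchange,
                       edge_key = split_key(side),
                       edge_key_labels = paste(tree$taxa[side],
                                               collapse = ","))))
}

#' Enumerate the NNI neighborhood
#'
#' @param tree A binary `phylo_tree`.
#' @return List of `nni_move` objects; `2(n-3)` of them for `n` leaves
#'   (empty for fewer than 4 leaves).
#' @examples
#' length(enumerate_nni_moves(parse_newick("((a,(b,c)),(d,(e,f)));")))
#' @export
enumerate_nni_moves <- function(tree) {
  stopifnot(is_phylo_tree(tree))
  check_binary(tree)
  k <- tree$n_leaf
  if (k < 4L) return(list())
  em <- tree_edge_matrix(tree)
  interior <- em[em[, 1L] > k & em[, 2L] > k, , drop = FALSE]
  moves <- vector("list", 2L * nrow(interior))
  for (i in seq_len(nrow(interior))) {
    ctx <- resolve_nni_context_nodes(tree, interior[i, 1L], interior[i, 2L])
    moves[[2L * i - 1L]] <- nni_move_from_context(tree, ctx, "AC")
    moves[[2L * i]] <- nni_move_from_context(tree, ctx, "AD")
  }
  moves
}

#' Apply an NNI move
#'
#' Returns a new tree; the input is never modified.  The result differs from
#' the input in exactly one split, so the RF distance is always 2.
#'
#' @param tree The tree the move was built on.
#' @param move An `nni_move`.
#' @return A `phylo_tree`.
#' @export
apply_nni <- function(tree, move) {
  stopifnot(inherits(move, "nni_move"))
  check_move(tree, move)
  adj <- tree$adj
  x <- move$a_node
  y <- if (move$exchange == "AC") move$c_node else move$d_node
  u <- move$u; v <- move$v
  adj[[u]][adj[[u]] == x] <- y
  adj[[v]][adj[[v]] == y] <- x
  adj[[x]][adj[[x]] == u] <- v
  adj[[y]][adj[[y]] == v] <- u
  new_phylo_tree(tree$taxa, tree$leaves, adj)
}

# ---------------------------------------------------------------------------
# SPR

# Shortest-path bookkeeping: parents of every node reachable from `start`
# without entering `block`.
bfs_parents <- function(tree, start, block) {
  N <- length(tree$adj)
  parent <- rep(NA_integer_, N)
  dist <- rep(NA_integer_, N)
  dist[start] <- 0L
  queue <- start
  if (!is.na(block)) dist[block] <- -1L
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    for (w in tree$adj[[u]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[u] + 1L
        parent[w] <- u
        queue <- c(queue, w)
      }
    }
  }
  if (!is.na(block)) dist[block] <- NA_integer_
  list(parent = parent, dist = dist)
}

path_to <- function(parents, node) {
  p <- node
  out <- node
  while (!is.na(parents$parent[p])) {
    p <- parents$parent[p]
    out <- c(p, out)
  }
  out
}

#' Construct an SPR move
#'
#' The subtree with taxon set `A` (one side of `prune`) is pruned and
#' regrafted onto `regraft`.  The path from the pruning attachment node to
#' the regraft edge resolves the side subtrees `B_1, ..., B_n` (with `B_n`
#' the component beyond the regraft edge); `n >= 3`, and `n = 3` is the
#' NNI-equivalent case.
#'
#' @param tree A binary `phylo_tree` with at least 4 leaves.
#' @param prune One side of an edge's split; that side is the pruned
#'   subtree `A`.
#' @param regraft One side of the regraft edge's split.  The edge must lie
#'   outside `A` and must not be incident to `A`'s attachment node.
#' @return An object of class `spr_move` with fields `A`, `B` (list of
#'   taxon-rank sets), `n`, and `nni_equivalent`.
#' @export
build_spr_move <- function(tree, prune, regraft) {
  stopifnot(is_phylo_tree(tree))
  check_binary(tree)
  if (tree$n_leaf < 4L) stop("SPR needs a tree with at least 4 leaves")
  pe <- find_edge(tree, prune)
  w <- pe$u; p <- pe$v                  # A beyond p, attachment node w
  if (w <= tree$n_leaf) {
    stop("pruning this side would leave a single leaf; prune the other side")
  }
  re <- find_edge(tree, regraft)
  a_nodes <- nodes_beyond(tree, w, p)
  if (re$u %in% a_nodes || re$v %in% a_nodes ||
      (re$u == w && re$v == p) || (re$u == p && re$v == w)) {
    stop("regraft edge must lie outside the pruned subtree")
  }
  bp <- bfs_parents(tree, w, p)
  near_v <- re$v
  far_v <- re$u
  if (bp$dist[re$u] < bp$dist[re$v]) { near_v <- re$u; far_v <- re$v }
  if (near_v == w) {
    stop("regraft edge is incident to the attachment node (identity move)")
  }
  P <- path_to(bp, near_v)              # w = v_1, ..., v_{n-1} = near_v
  n <- length(P) + 1L
  B <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    excl <- c(if (i > 1L) P[i - 1L] else p,
              if (i < n - 1L) P[i + 1L] else far_v)
    third <- setdiff(tree$adj[[P[i]]], excl)
    B[[i]] <- leafset_beyond(tree, P[i], third)
  }
  B[[n]] <- leafset_beyond(tree, near_v, far_v)
  new_move("SPR", tree,
           list(A = pe$side, B = B, n = n,
                w = w, p = p, s = near_v, t = far_v, path = P,
                nni_equivalent = (n == 3L)))
}

#' Apply an SPR move
#'
#' The split symmetric difference between input and output is the predicted
#' family of path-edge splits, so the RF distance equals `2(n - 2)`.
#'
#' @param tree The tree the move was built on.
#' @param move An `spr_move`.
#' @return A `phylo_tree`; the input is unmodified.
#' @export
apply_spr <- function(tree, move) {
  stopifnot(inherits(move, "spr_move"))
  check_move(tree, move)
  adj <- tree$adj
  w <- move$w; p <- move$p; s <- move$s; t <- move$t
  xy <- setdiff(adj[[w]], p)
  adj[[xy[1L]]][adj[[xy[1L]]] == w] <- xy[2L]
  adj[[xy[2L]]][adj[[xy[2L]]] == w] <- xy[1L]
  adj[[s]][adj[[s]] == t] <- w
  adj[[t]][adj[[t]] == s] <- w
  adj[[w]] <- c(s, t, p)
  new_phylo_tree(tree$taxa, tree$leaves, adj)
}

# ---------------------------------------------------------------------------
# TBR

# Path decomposition of one component after bisection: from bisect endpoint
# `u` (partner `v`) to the reconnect edge found at (near, far).
tbr_side_paths <- function(tree, u, v, near_v, far_v, parents) {
  P <- path_to(parents, near_v)         # u = u_1, ..., u_{n-1} = near_v
  n <- length(P) + 1L
  S <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    excl <- c(if (i > 1L) P[i - 1L] else v,
              if (i < n - 1L) P[i + 1L] else far_v)
    third <- setdiff(tree$adj[[P[i]]], excl)
    S[[i]] <- leafset_beyond(tree, P[i], third)
  }
  S[[n]] <- leafset_beyond(tree, near_v, far_v)
  list(S = S, n = n, path = P)
}

#' Construct a TBR move
#'
#' The tree is bisected at `bisect`; the two components are reconnected by a
#' new edge joining the midpoints of `reconnect_b` and `reconnect_c`, which
#' must lie in different components.  The side subtrees `B_1..B_n` and
#' `C_1..C_m` are resolved along the paths from the bisection endpoints to
#' the reconnect edges; the B side is the component containing
#' `reconnect_b`.  `n = m = 2` (both reconnect edges adjacent to the
#' bisection) is the identity and is rejected.
#'
#' @param tree A binary `phylo_tree` with at least 4 leaves.
#' @param bisect One side of the bisection edge's split.
#' @param reconnect_b,reconnect_c One side of each reconnect edge's split.
#' @return An object of class `tbr_move` with fields `B`, `C`, `n`, `m` and
#'   `equivalent` (`"NNI"`, `"SPR"` or `NULL`).
#' @export
build_tbr_move <- function(tree, bisect, reconnect_b, reconnect_c) {
  stopifnot(is_phylo_tree(tree))
  check_binary(tree)
  if (tree$n_leaf < 4L) stop("TBR needs a tree with at least 4 leaves")
  be <- find_edge(tree, bisect)
  rb <- find_edge(tree, reconnect_b)
  rc <- find_edge(tree, reconnect_c)
  comp_v <- nodes_beyond(tree, be$u, be$v)
  in_v <- function(e) {
    iu <- e$u %in% comp_v; iv <- e$v %in% comp_v
    if (iu != iv) stop("a reconnect edge coincides with the bisection edge")
    iu
  }
  rb_in_v <- in_v(rb); rc_in_v <- in_v(rc)
  if (rb_in_v == rc_in_v) {
    stop("reconnect edges must lie in the two different components ",
         "created by the bisection")
  }
  u <- if (rb_in_v) be$v else be$u      # bisect endpoint in the B component
  v <- if (rb_in_v) be$u else be$v
  orient <- function(e, start, block) {
    bp <- bfs_parents(tree, start, block)
    if (bp$dist[e$u] < bp$dist[e$v]) list(near = e$u, far = e$v, bp = bp)
    else list(near = e$v, far = e$u, bp = bp)
  }
  ob <- orient(rb, u, v)
  oc <- orient(rc, v, u)
  bside <- tbr_side_paths(tree, u, v, ob$near, ob$far, ob$bp)
  cside <- tbr_side_paths(tree, v, u, oc$near, oc$far, oc$bp)
  if (bside$n == 2L && cside$n == 2L) {
    stop("both reconnect edges are adjacent to the bisection (identity move)")
  }
  nm <- sort(c(bside$n, cside$n))
  equivalent <- if (nm[1L] == 2L && nm[2L] == 3L) "NNI"
                else if (nm[1L] == 2L) "SPR" else NULL
  new_move("TBR", tree,
           list(B = bside$S, C = cside$S, n = bside$n, m = cside$n,
                u = u, v = v,
                s_b = ob$near, t_b = ob$far, s_c = oc$near, t_c = oc$far,
                path_b = bside$path, path_c = cside$path,
                equivalent = equivalent))
}

#' Apply a TBR move
#'
#' The bisection split itself is preserved; the path-edge splits on both
#' sides change, giving RF distance `2(n + m - 4)`.
#'
#' @param tree The tree the move was built on.
#' @param move A `tbr_move`.
#' @return A `phylo_tree`; the input is unmodified.
#' @export
apply_tbr <- function(tree, move) {
  stopifnot(inherits(move, "tbr_move"))
  check_move(tree, move)
  adj <- tree$adj
  u <- move$u; v <- move$v
  adj[[u]] <- setdiff(adj[[u]], v)
  adj[[v]] <- setdiff(adj[[v]], u)
  drop_node <- function(node, pair) {
    nb <- adj[[node]]
    if (pair[1L] == node) pair <- nb    # reconnect edge merged by suppression
    adj[[nb[1L]]][adj[[nb[1L]]] == node] <<- nb[2L]
    adj[[nb[2L]]][adj[[nb[2L]]] == node] <<- nb[1L]
    adj[[node]] <<- integer(0)
    pair
  }
  rbp <- drop_node(u, c(move$s_b, move$t_b))
  rcp <- drop_node(v, c(move$s_c, move$t_c))
  subdivide <- function(pair, mid) {
    adj[[pair[1L]]][adj[[pair[1L]]] == pair[2L]] <<- mid
    adj[[pair[2L]]][adj[[pair[2L]]] == pair[1L]] <<- mid
    adj[[mid]] <<- pair
  }
  subdivide(rbp, u)
  subdivide(rcp, v)
  adj[[u]] <- c(adj[[u]], v)
  adj[[v]] <- c(adj[[v]], u)
  new_phylo_tree(tree$taxa, tree$leaves, adj)
}

# ---------------------------------------------------------------------------
# Shared move interface

#' Apply any rearrangement move
#' @param tree The tree the move was built on.
#' @param move An `nni_move`, `spr_move` or `tbr_move`.
#' @return A `phylo_tree`.
#' @export
apply_move <- function(tree, move) {
  switch(move$kind,
         NNI = apply_nni(tree, move),
         SPR = apply_spr(tree, move),
         TBR = apply_tbr(tree, move),
         stop("unknown move kind"))
}

#' Predicted Robinson-Foulds distance of a move
#'
#' Closed forms: 2 for an NNI, `2(n - 2)` for an SPR with path parameter
#' `n`, `2(n + m - 4)` for a TBR.  Always equals
#' `rf_distance(tree, apply_move(tree, move))`.
#'
#' @param move A resolved move.
#' @return A non-negative even integer.
#' @export
predicted_rf <- function(move) {
  switch(move$kind,
         NNI = 2L,
         SPR = 2L * (move$n - 2L),
         TBR = 2L * (move$n + move$m - 4L),
         stop("unknown move kind"))
}

#' Predicted changed splits of a move
#'
#' The symmetric difference between the split sets of the tree and of the
#' rearranged tree, expressed through the move's context taxon sets:
#' for an NNI exchanging A with C it is `{A+B | C+D, A+D | B+C}`; for an SPR
#' the two families of path-edge splits; for a TBR the four families (the
#' bisection split itself is preserved).
#'
#' @param move A resolved move.
#' @return Character vector of canonical split keys (see [splits_of()]).
#' @export
predicted_changed_splits <- function(move) {
  lr <- move$leaf_ranks
  key <- function(ranks) split_key(canonical_side(sort(ranks), lr))
  cum_union <- function(sets, upto) sort(unlist(sets[seq_len(upto)]))
  out <- character(0)
  if (move$kind == "NNI") {
    e_old <- c(move$A, move$B)
    e_new <- if (move$exchange == "AC") c(move$A, move$D) else
      c(move$A, move$C)
    out <- c(key(e_old), key(e_new))
  } else if (move$kind == "SPR") {
    n <- move$n
    for (x in seq_len(n - 2L)) {
      out <- c(out, key(c(move$A, cum_union(move$B, x))))
    }
    for (x in 2L:(n - 1L)) {
      out <- c(out, key(cum_union(move$B, x)))
    }
  } else if (move$kind == "TBR") {
    n <- move$n; m <- move$m
    allC <- sort(unlist(move$C))
    allB <- sort(unlist(move$B))
    if (n > 2L) {
      for (x in seq_len(n - 2L)) {
        out <- c(out, key(c(allC, cum_union(move$B, x))))
      }
      for (x in 2L:(n - 1L)) out <- c(out, key(cum_union(move$B, x)))
    }
    if (m > 2L) {
      for (y in seq_len(m - 2L)) {
        out <- c(out, key(c(allB, cum_union(move$C, y))))
      }
      for (y in 2L:(m - 1L)) out <- c(out, key(cum_union(move$C, y)))
    }
  } else {
    stop("unknown move kind")
  }
  unique(out)
}

# ---------------------------------------------------------------------------
# Radius-capped enumeration plumbing for SPR and TBR sweeps.

#' Enumerate SPR moves up to a path-length radius
#'
#' All (prune edge orientation, regraft edge) pairs whose path parameter `n`
#' satisfies `3 <= n <= radius`.  Tree searches typically use short SPR, so
#' the default radius is 5.
#'
#' @param tree A binary `phylo_tree`.
#' @param radius Maximum path parameter `n` (use `Inf` for all moves).
#' @return List of `spr_move` objects.
#' @export
enumerate_spr_moves <- function(tree, radius = 5) {
  stopifnot(is_phylo_tree(tree))
  k <- tree$n_leaf
  if (k < 4L) return(list())
  em <- tree_edge_matrix(tree)
  moves <- list()
  for (i in seq_len(nrow(em))) {
    for (flip in c(FALSE, TRUE)) {
      w <- if (flip) em[i, 2L] else em[i, 1L]
      p <- if (flip) em[i, 1L] else em[i, 2L]
      if (w <= k) next                  # remaining tree would be one leaf
      aside <- leafset_beyond(tree, w, p)
      a_nodes <- c(p, nodes_beyond(tree, w, p))
      bp <- bfs_parents(tree, w, p)
      for (j in seq_len(nrow(em))) {
        s <- em[j, 1L]; t <- em[j, 2L]
        if (s %in% a_nodes || t %in% a_nodes) next
        d <- min(bp$dist[s], bp$dist[t])
        n <- d + 2L
        if (n < 3L || n > radius) next
        moves[[length(moves) + 1L]] <-
          build_spr_move(tree, aside, leafset_beyond(tree, s, t))
      }
    }
  }
  moves
}

#' Enumerate TBR moves up to side-path radii
#'
#' All (bisection, reconnect pair) combinations with both side parameters at
#' most `radius` (and not both equal to 2, the identity).
#'
#' @inheritParams enumerate_spr_moves
#' @return List of `tbr_move` objects.
#' @export
enumerate_tbr_moves <- function(tree, radius = 5) {
  stopifnot(is_phylo_tree(tree))
  k <- tree$n_leaf
  if (k < 4L) return(list())
  em <- tree_edge_matrix(tree)
  interior <- em[em[, 1L] > k & em[, 2L] > k, , drop = FALSE]
  moves <- list()
  for (i in seq_len(nrow(interior))) {
    u <- interior[i, 1L]; v <- interior[i, 2L]
    comp_v <- nodes_beyond(tree, u, v)
    bu <- bfs_parents(tree, u, v)
    bv <- bfs_parents(tree, v, u)
    cand <- function(bp, comp) {
      idx <- which(apply(em, 1L, function(e) (e[1L] %in% comp) &&
                                             (e[2L] %in% comp)))
      ns <- vapply(idx, function(j) {
        min(bp$dist[em[j, 1L]], bp$dist[em[j, 2L]]) + 2L
      }, 0L)
      idx[ns <= radius]
    }
    comp_u <- setdiff(seq_along(tree$adj), c(comp_v))
    bcand <- cand(bu, comp_u)
    ccand <- cand(bv, comp_v)
    eside <- leafset_beyond(tree, v, u)
    for (jb in bcand) {
      for (jc in ccand) {
        mv <- tryCatch(
          build_tbr_move(tree, eside,
                         leafset_beyond(tree, em[jb, 1L], em[jb, 2L]),
                         leafset_beyond(tree, em[jc, 1L], em[jc, 2L])),
          error = function(e) NULL)
        if (!is.null(mv)) moves[[length(moves) + 1L]] <- mv
      }
    }
  }
  moves
}

# ---------------------------------------------------------------------------
# Serialization for the command-line interface: edges are identified by the
# sorted taxon list of the smaller side of their split.

smaller_side_labels <- function(move, ranks) {
  taxa <- move$taxa
  other <- setdiff(move$leaf_ranks, ranks)
  side <- if (length(ranks) <= length(other)) ranks else other
  sort_labels(taxa[side])
}

#' Serialize a move to a JSON-ready list
#' @param move A `phylo_move`.
#' @return A named list (convert with `jsonlite::toJSON`).
#' @export
move_to_record <- function(move) {
  if (move$kind == "NNI") {
    list(kind = "NNI",
         edge = smaller_side_labels(move, sort(c(move$A, move$B))),
         exchange = move$exchange)
  } else if (move$kind == "SPR") {
    list(kind = "SPR",
         prune = smaller_side_labels(move, move$A),
         regraft = smaller_side_labels(move, move$B[[move$n]]),
         n = move$n)
  } else {
    list(kind = "TBR",
         bisect = smaller_side_labels(move, sort(unlist(move$B))),
         reconnect_b = smaller_side_labels(move, move$B[[move$n]]),
         reconnect_c = smaller_side_labels(move, move$C[[move$m]]),
         n = move$n, m = move$m)
  }
}
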