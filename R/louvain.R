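# Shared plumbing between the two algorithms.

move_nodes_raw <- function(g, memb, spec, fast) {
  cpp_move_nodes(g$indptr, g$nbr - 1L, g$wt, node_mass(g, spec),
                 as.integer(memb) - 1L, gamma_eff(g, spec), 1e-12, fast) + 1L
}

#' Louvain local moving phase
#'
#' Sweeps all nodes in a fresh random order, greedily moving each node to the
#' community (including a fresh empty one) with the largest quality gain, and
#' repeats until a full sweep makes no move. Quality is non-decreasing and the
#' returned partition is node optimal. Ties keep the current community,
#' otherwise the lowest community label wins.
#'
#' @param g an `ldn_graph`.
#' @param p starting `ldn_partition`.
#' @param spec an `ldn_qspec`.
#' @return the locally optimal `ldn_partition`.
#' @export
louvain_move_nodes <- function(g, p, spec) {
  partition(g, move_nodes_raw(g, p$memb, spec, fast = FALSE))
}

#' Fast local move phase
#'
#' Queue-based local moving: the queue starts with all nodes in random order;
#' when a node moves, its neighbours outside the new community re-enter the
#' queue. After the queue drains, a verification sweep re-checks every node
#' (and refills the queue if anything still improves), so the returned
#' partition is node optimal like [louvain_move_nodes()], while revisiting far
#' fewer nodes on the way.
#'
#' @inheritParams louvain_move_nodes
#' @return the locally optimal `ldn_partition`.
#' @export
fast_local_move <- function(g, p, spec) {
  partition(g, move_nodes_raw(g, p$memb, spec, fast = TRUE))
}

# One multi-level pass of Louvain or Leiden. Returns the membership vector on
# the original nodes. `theta = NULL` selects Louvain (aggregate on P itself,
# singleton restart at each aggregate level); otherwise Leiden (fast local
# move, theta-randomized refinement, aggregation on the refined partition with
# P inducing the initial aggregate partition).
one_iteration_memb <- function(g, memb, spec, theta = NULL) {
  g_cur <- g
  proj <- seq_len(g$n)
  memb_cur <- canonical_membership(memb)
  repeat {
    fast <- !is.null(theta)
    memb_cur <- canonical_membership(move_nodes_raw(g_cur, memb_cur, spec, fast = fast))
    C <- max(memb_cur)
    if (is.null(theta)) {
      proj <- memb_cur[proj]
      if (C == g_cur$n) break
      g_cur <- aggregate_graph(g_cur, partition(g_cur, memb_cur))$graph
      memb_cur <- seq_len(C)
    } else {
      if (C == g_cur$n) {          # every community a single node: done
        proj <- memb_cur[proj]
        break
      }
      rl <- NULL
      for (try in 1:20) {          # refinement can tie itself into singletons;
        rl <- canonical_membership(  # retry -- a mergeable pair always exists
          cpp_refine(g_cur$indptr, g_cur$nbr - 1L, g_cur$wt,
                     node_mass(g_cur, spec), memb_cur - 1L,
                     seq_len(g_cur$n) - 1L, gamma_eff(g_cur, spec),
                     theta, 1e-12, -1L) + 1L)
        if (max(rl) < g_cur$n) break
      }
      R <- max(rl)
      if (R == g_cur$n) {          # stagnated: accept the current partition
        proj <- memb_cur[proj]
        break
      }
      rp <- partition(g_cur, rl)
      agg <- aggregate_graph(g_cur, rp)$graph
      # initial aggregate partition: each refined community inherits its
      # community in the non-refined partition P
      first_member <- match(seq_len(R), rl)
      memb_agg <- canonical_membership(memb_cur[first_member])
      proj <- rl[proj]
      g_cur <- agg
      memb_cur <- memb_agg
    }
  }
  canonical_membership(proj)
}

#' One Louvain iteration
#'
#' Alternates [louvain_move_nodes()] with aggregation, restarting each
#' aggregate level from singletons, until the aggregate level makes no further
#' change; the final aggregate-level partition is lifted back to the original
#' nodes. Quality is non-decreasing.
#'
#' @inheritParams louvain_move_nodes
#' @return an `ldn_partition` on the original nodes.
#' @export
louvain_iteration <- function(g, p, spec) {
  partition(g, one_iteration_memb(g, p$memb, spec, theta = NULL))
}
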