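#' Randomized node merging within one community
#'
#' Implements the refinement step restricted to a single community `S` of the
#' non-refined partition. Nodes of `S` that are still singletons in `refined`
#' and are well connected within `S` are visited in random order; each may
#' merge into a refined community `C` inside `S` that is itself well connected
#' within `S`. Among the candidate targets with non-negative quality change
#' (staying put always included), one is drawn with probability proportional to
#' `exp(delta / theta)`; quality-decreasing mergers have probability zero, so
#' quality never decreases. As `theta -> 0` the choice concentrates on the
#' greedy argmax.
#'
#' Well-connectedness of a node/community `X` within `S` is the cut bound
#' `E(X, S \ X) >= gamma_eff * a_X * (a_S - a_X)` with `a` the node size (CPM)
#' or strength with `gamma_eff = gamma / (2m)` (modularity).
#'
#' @param g an `ldn_graph`.
#' @param refined an `ldn_partition` in which every node of `subset` is a
#'   singleton.
#' @param subset node ids of one community of the non-refined partition.
#' @param spec an `ldn_qspec`.
#' @param theta positive randomness parameter.
#' @return the updated `ldn_partition`.
#' @export
merge_nodes_subset <- function(g, refined, subset, spec, theta = 0.01) {
  subset <- sort(unique(as.integer(subset)))
  if (!length(subset)) stop("`subset` must be nonempty")
  if (theta <= 0) stop("`theta` must be positive")
  if (any(refined$csize[refined$memb[subset]] != 1L))
    stop("every node of `subset` must be a singleton in `refined`")
  pmemb <- rep(1L, g$n)
  pmemb[subset] <- 0L
  rl <- cpp_refine(g$indptr, g$nbr - 1L, g$wt, node_mass(g, spec),
                   pmemb, refined$memb - 1L, gamma_eff(g, spec),
                   theta, 1e-12, 0L) + 1L
  partition(g, rl)
}

#' Refine a partition into well-connected subcommunities
#'
#' Starts from the all-singleton partition and applies [merge_nodes_subset()]
#' to every community of `p`. The result always refines `p` (every refined
#' community is a subset of a community of `p`) and every refined community
#' induces a connected subgraph, because merges require a positive connection.
#'
#' @param g an `ldn_graph`.
#' @param p the non-refined `ldn_partition`.
#' @param spec an `ldn_qspec`.
#' @param theta positive randomness parameter (default 0.01).
#' @return the refined `ldn_partition`.
#' @export
refine_partition <- function(g, p, spec, theta = 0.01) {
  if (theta <= 0) stop("`theta` must be positive")
  rl <- cpp_refine(g$indptr, g$nbr - 1L, g$wt, node_mass(g, spec),
                   p$memb - 1L, seq_len(g$n) - 1L, gamma_eff(g, spec),
                   theta, 1e-12, -1L) + 1L
  partition(g, rl)
}

#' One Leiden iteration
#'
#' Loops over levels: fast local move, refinement, then aggregation on the
#' refined partition with the non-refined partition inducing the initial
#' aggregate assignment, recursing on the aggregate until every community is a
#' single node. The result is lifted back to the original nodes. After each
#' iteration every community is connected and the partition is
#' gamma-separated; quality is non-decreasing.
#'
#' @param g an `ldn_graph`.
#' @param p starting `ldn_partition`.
#' @param spec an `ldn_qspec`.
#' @param theta positive randomness parameter for the refinement phase.
#' @return an `ldn_partition` on the original nodes.
#' @export
leiden_iteration <- function(g, p, spec, theta = 0.01) {
  if (theta <= 0) stop("`theta` must be positive")
  partition(g, one_iteration_memb(g, p$memb, spec, theta = theta))
}
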