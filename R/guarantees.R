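# Checkers for the hierarchy of guarantees, plus the badly-connected audit.
#
# Hierarchy (strongest last): connectivity and gamma-separation hold after
# every Leiden iteration; node optimality and subpartition gamma-density after
# a stable iteration; uniform gamma-density and subset optimality after
# convergence. The exhaustive checkers enumerate bipartitions/subsets and are
# capped at communities of `max_exhaustive` nodes.

cut_weight <- function(g, A, B) {
  inA <- rep(FALSE, g$n); inA[A] <- TRUE
  inB <- rep(FALSE, g$n); inB[B] <- TRUE
  e <- g$edges
  sum(e$w[(inA[e$i] & inB[e$j]) | (inB[e$i] & inA[e$j])])
}

#' Is a partition gamma-separated?
#'
#' `TRUE` iff no pair of communities can be merged with a quality gain, i.e.
#' [delta_merge()] is at most `tol` for every (adjacent) pair. This is the one
#' guarantee already provided by a completed Louvain run.
#'
#' @param g an `ldn_graph`.
#' @param p an `ldn_partition`.
#' @param spec an `ldn_qspec`.
#' @param tol numerical tolerance.
#' @export
is_gamma_separated <- function(g, p, spec, tol = 1e-9) {
  if (p$C < 2L) return(TRUE)
  e <- g$edges
  ci <- p$memb[e$i]; cj <- p$memb[e$j]
  ext <- ci != cj
  if (!any(ext)) return(TRUE)   # no adjacent pairs; all merge deltas negative
  a <- pmin(ci[ext], cj[ext]); b <- pmax(ci[ext], cj[ext])
  key <- (as.numeric(a) - 1) * p$C + b
  E12 <- rowsum(e$w[ext], group = key)
  kk <- as.numeric(rownames(E12))
  c1 <- as.integer((kk - 1) %/% p$C + 1)
  c2 <- as.integer(kk - (as.numeric(c1) - 1) * p$C)
  d <- if (spec$objective == "modularity")
    (2 * E12[, 1L] - 2 * spec$gamma * p$K[c1] * p$K[c2] / (2 * g$m)) / (2 * g$m)
  else
    E12[, 1L] - spec$gamma * p$nsize[c1] * p$nsize[c2]
  all(d <= tol)
}

#' Is every community internally connected?
#'
#' `TRUE` iff the subgraph induced by each community has a single connected
#' component. Guaranteed for Leiden output, not for Louvain.
#'
#' @param g an `ldn_graph`.
#' @param p an `ldn_partition`.
#' @export
is_connected_partition <- function(g, p) {
  for (c in seq_len(p$C)) {
    nodes <- which(p$memb == c)
    if (length(nodes) > 1L && max(component_ids(g, nodes)) > 1L) return(FALSE)
  }
  TRUE
}

#' Is every node locally optimally assigned?
#'
#' `TRUE` iff no single node can be moved to any other community (including a
#' fresh empty one) with a quality gain above `tol`.
#'
#' @inheritParams is_gamma_separated
#' @export
is_node_optimal <- function(g, p, spec, tol = 1e-9) {
  gam <- gamma_eff(g, spec)
  mass <- node_mass(g, spec)
  A <- comm_mass(p, spec)
  for (v in seq_len(g$n)) {
    r <- nbr_range(g, v)
    cv <- p$memb[v]
    mv <- mass[v]
    if (length(r)) {
      cc <- p$memb[g$nbr[r]]
      w <- rowsum(g$wt[r], group = cc)
      tgt <- as.integer(rownames(w))
      s <- w[, 1L] - gam * mv * (A[tgt] - (tgt == cv) * mv)
      cur <- if (cv %in% tgt) s[tgt == cv] else -gam * mv * (A[cv] - mv)
      if (max(c(s, 0)) > cur + tol) return(FALSE)
    } else {
      cur <- -gam * mv * (A[cv] - mv)
      if (0 > cur + tol) return(FALSE)
    }
  }
  TRUE
}

# all bipartitions (A, B) of `nodes` with both sides nonempty, as logical masks
bipartition_masks <- function(k) {
  if (k < 2L) return(list())
  lapply(seq_len(2L^(k - 1L) - 1L) - 1L, function(m) {
    bits <- as.logical(bitwAnd(m, 2L^(seq_len(k - 1L) - 1L)))
    c(TRUE, bits)   # first node pinned to side A: unordered bipartitions
  })
}

# E(X, comm \ X) >= gam * a_X * (a_comm - a_X), the "cannot be separated" /
# well-connectedness bound shared with the refinement phase
separation_ok <- function(g, spec, X, rest, aX, aC, tol) {
  cut_weight(g, X, rest) >= gamma_eff(g, spec) * aX * (aC - aX) - tol
}

#' Is a community subpartition gamma-dense?
#'
#' Recursive exhaustive check: a singleton is subpartition gamma-dense; a
#' larger community is, iff it admits a bipartition into two parts such that
#' (1) the parts are well connected to each other (`E(A, B) >= gamma_eff a_A
#' a_B`), (2) neither part can be separated from the community (the quality
#' delta of splitting the part off is <= 0), and (3) each part is itself
#' subpartition gamma-dense. Communities larger than `max_exhaustive` return
#' `NA` ("not checkable"), distinct from `FALSE`.
#'
#' @inheritParams is_gamma_separated
#' @param community community id in `1..C`.
#' @param max_exhaustive largest community size checked exhaustively.
#' @export
is_subpartition_gamma_dense <- function(g, p, spec, community, tol = 1e-9,
                                        max_exhaustive = 12L) {
  members <- which(p$memb == community)
  if (length(members) > max_exhaustive) return(NA)
  gam <- gamma_eff(g, spec)
  mass <- node_mass(g, spec)
  aC <- sum(mass[members])
  memo <- new.env(parent = emptyenv())
  check <- function(nodes) {
    k <- length(nodes)
    if (k == 1L) return(TRUE)
    key <- paste(nodes, collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- FALSE
    for (mask in bipartition_masks(k)) {
      A <- nodes[mask]; B <- nodes[!mask]
      aA <- sum(mass[A]); aB <- sum(mass[B])
      if (cut_weight(g, A, B) < gam * aA * aB - tol) next           # (1)
      if (!separation_ok(g, spec, A, setdiff(members, A), aA, aC, tol)) next  # (2)
      if (!separation_ok(g, spec, B, setdiff(members, B), aB, aC, tol)) next
      if (check(A) && check(B)) { res <- TRUE; break }              # (3)
    }
    memo[[key]] <- res
    res
  }
  check(members)
}

#' Is a community uniformly gamma-dense?
#'
#' `TRUE` iff every bipartition `(A, B)` of the community satisfies
#' `E(A, B) >= gamma_eff * a_A * a_B`: no subset can be separated, however the
#' community is cut in two. Communities larger than `max_exhaustive` return
#' `NA`.
#'
#' @inheritParams is_subpartition_gamma_dense
#' @export
is_uniformly_gamma_dense <- function(g, p, spec, community, tol = 1e-9,
                                     max_exhaustive = 12L) {
  members <- which(p$memb == community)
  if (length(members) > max_exhaustive) return(NA)
  if (length(members) == 1L) return(TRUE)
  gam <- gamma_eff(g, spec)
  mass <- node_mass(g, spec)
  for (mask in bipartition_masks(length(members))) {
    A <- members[mask]; B <- members[!mask]
    if (cut_weight(g, A, B) < gam * sum(mass[A]) * sum(mass[B]) - tol)
      return(FALSE)
  }
  TRUE
}

# quality delta of moving node set A from community `cfrom` to `cto`
# (0 = fresh); exact for both objectives, shares the score algebra of
# delta_move generalized to sets
delta_move_set <- function(g, p, A, cto, spec) {
  cfrom <- p$memb[A[1L]]
  gam <- gamma_eff(g, spec)
  mass <- node_mass(g, spec)
  Am <- comm_mass(p, spec)
  aA <- sum(mass[A])
  restfrom <- setdiff(which(p$memb == cfrom), A)
  s_old <- cut_weight(g, A, restfrom) - gam * aA * (Am[cfrom] - aA)
  s_new <- if (cto == 0L) 0 else
    cut_weight(g, A, which(p$memb == cto)) - gam * aA * Am[cto]
  delta_scale(g, spec) * (s_new - s_old)
}

#' Is a community subset optimal?
#'
#' `TRUE` iff no nonempty subset of the community can be moved to any other
#' community (including a fresh empty one) with a quality gain above `tol`.
#' This is the strongest guarantee in the hierarchy; it implies uniform
#' gamma-density and all weaker properties. Communities larger than
#' `max_exhaustive` return `NA`.
#'
#' @inheritParams is_subpartition_gamma_dense
#' @export
is_subset_optimal <- function(g, p, spec, community, tol = 1e-9,
                              max_exhaustive = 12L) {
  members <- which(p$memb == community)
  k <- length(members)
  if (k > max_exhaustive) return(NA)
  targets <- c(0L, setdiff(seq_len(p$C), community))
  for (m in seq_len(2L^k - 1L)) {
    A <- members[as.logical(bitwAnd(m, 2L^(seq_len(k) - 1L)))]
    for (t in targets) {
      if (delta_move_set(g, p, A, t, spec) > tol) return(FALSE)
    }
  }
  TRUE
}

#' Audit a partition for disconnected and badly connected communities
#'
#' For each community, checks internal connectivity and re-clusters the
#' community's subnetwork with Leiden (run until a stable iteration). The
#' subnetwork quality is evaluated consistently with the full network: for
#' modularity the subgraph keeps the full graph's total edge weight `m` and
#' the original node strengths (CPM is local and needs no adjustment). A
#' community that the subnetwork run splits into more than one community is
#' counted as badly connected -- splitting it is then guaranteed to increase
#' the (consistent) quality, and the reported `split_gain` is that increase.
#' Disconnected communities are counted among the badly connected ones.
#'
#' The audit is a lower bound: a community the audit does not split is not
#' thereby certified well connected.
#'
#' @param g an `ldn_graph`.
#' @param p the `ldn_partition` to audit.
#' @param spec an `ldn_qspec`.
#' @param config an [`ldn_config`][leiden_config] for the subnetwork runs.
#' @return an object of class `ldn_audit`: `per_community` data frame
#'   (community, size, connected, badly_connected, n_subcommunities,
#'   split_gain) and summary percentages `pct_disconnected`,
#'   `pct_badly_connected`.
#' @export
audit_partition <- function(g, p, spec,
                            config = leiden_config(stop_policy = "until_stable",
                                                   max_iterations = 50L)) {
  C <- p$C
  connected <- logical(C)
  nsub <- integer(C)
  gain <- numeric(C)
  for (c in seq_len(C)) {
    nodes <- which(p$memb == c)
    if (length(nodes) == 1L) {
      connected[c] <- TRUE; nsub[c] <- 1L; gain[c] <- 0
      next
    }
    sub <- induced_subgraph(g, nodes, keep_scale = TRUE)$graph
    connected[c] <- length(graph_components(sub)) == 1L
    run <- run_algorithm(sub, spec, "leiden", config)
    nsub[c] <- run$partition$C
    if (nsub[c] > 1L) {
      one <- partition(sub, rep(1L, sub$n))
      gain[c] <- quality(sub, run$partition, spec) - quality(sub, one, spec)
    }
  }
  badly <- !connected | nsub > 1L
  structure(list(
    per_community = data.frame(
      community = seq_len(C),
      size = p$csize,
      connected = connected,
      badly_connected = badly,
      n_subcommunities = nsub,
      split_gain = gain
    ),
    pct_disconnected = 100 * mean(!connected),
    pct_badly_connected = 100 * mean(badly)
  ), class = "ldn_audit")
}

#' @export
print.ldn_audit <- function(x, ...) {
  cat(sprintf("partition audit over %d communities\n", nrow(x$per_community)))
  cat(sprintf("  disconnected:    %5.1f%%\n", x$pct_disconnected))
  cat(sprintf("  badly connected: %5.1f%%\n", x$pct_badly_connected))
  flagged <- x$per_community[x$per_community$badly_connected, , drop = FALSE]
  if (nrow(flagged)) {
    cat("  flagged communities:\n")
    print(flagged, row.names = FALSE)
  }
  invisible(x)
}
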