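#' Quality specification
#'
#' Chooses the objective to optimise: modularity
#' \deqn{H = \frac{1}{2m}\sum_c \left(2 e_c - \gamma \frac{K_c^2}{2m}\right)}
#' (with \eqn{e_c} the internal edge weight of community \eqn{c}, \eqn{K_c} the
#' summed strengths and \eqn{m} the total edge weight), or the Constant Potts
#' Model (CPM)
#' \deqn{H = \sum_c \left[e_c - \gamma \frac{n_c(n_c-1)}{2}\right]}
#' with \eqn{n_c} the summed node sizes of the community (the binomial
#' coefficient for unit sizes). Under CPM, \eqn{\gamma} is a density threshold:
#' communities should be denser than \eqn{\gamma} inside and sparser than
#' \eqn{\gamma} between.
#'
#' @param objective `"cpm"` or `"modularity"`.
#' @param gamma positive resolution parameter (default 1).
#' @return an object of class `ldn_qspec`.
#' @export
quality_spec <- function(objective = c("cpm", "modularity"), gamma = 1) {
  objective <- match.arg(objective)
  gamma <- as.numeric(gamma)
  if (length(gamma) != 1L || is.na(gamma) || gamma <= 0)
    stop("`gamma` must be a single positive number")
  structure(list(objective = objective, gamma = gamma), class = "ldn_qspec")
}

# Unified delta machinery: for both objectives the quality change of moving
# node mass between communities is a positive constant times a difference of
#   score(v -> c) = w(v, c \ v) - gam_eff * mass_v * (A_c - [v in c] mass_v)
# with (mass, A, gam_eff, scale) as below.
gamma_eff <- function(g, spec) {
  if (spec$objective == "modularity") spec$gamma / (2 * g$m) else spec$gamma
}
node_mass <- function(g, spec) {
  if (spec$objective == "modularity") g$strength else g$size
}
comm_mass <- function(p, spec) {
  if (spec$objective == "modularity") p$K else p$nsize
}
delta_scale <- function(g, spec) {
  if (spec$objective == "modularity") 1 / g$m else 1
}

#' Partition of a graph
#'
#' Stores a per-node community membership (relabelled to contiguous `1..C`)
#' together with cached per-community aggregates: internal edge weight `E`
#' (each unordered pair once, self-loops fully internal), summed strengths `K`,
#' summed node sizes `nsize` and member counts `csize`.
#'
#' @param g an [`ldn_graph`][graph_from_edges].
#' @param membership community label per node (any integers; relabelled).
#' @return an object of class `ldn_partition`.
#' @export
partition <- function(g, membership) {
  mm <- as.integer(membership)
  if (length(mm) != g$n || anyNA(mm))
    stop("membership must assign every node to exactly one community")
  cl <- match(mm, sort(unique(mm)))
  C <- max(cl)
  vsum <- function(x, f) {
    out <- numeric(C)
    r <- rowsum(x, group = f)
    out[as.integer(rownames(r))] <- r[, 1L]
    out
  }
  e <- g$edges
  internal <- cl[e$i] == cl[e$j]
  E <- if (any(internal)) vsum(e$w[internal], cl[e$i[internal]]) else numeric(C)
  structure(list(
    memb = cl,
    C = C,
    E = E,
    K = vsum(g$strength, cl),
    nsize = vsum(g$size, cl),
    csize = tabulate(cl, nbins = C)
  ), class = "ldn_partition")
}

#' All-singleton partition
#' @param g an `ldn_graph`.
#' @return an `ldn_partition` with every node in its own community.
#' @export
singleton_partition <- function(g) partition(g, seq_len(g$n))

# canonical first-appearance relabelling, for partition equality up to labels
canonical_membership <- function(memb) match(memb, unique(memb))

same_partition <- function(a, b) {
  ma <- if (inherits(a, "ldn_partition")) a$memb else a
  mb <- if (inherits(b, "ldn_partition")) b$memb else b
  identical(canonical_membership(ma), canonical_membership(mb))
}

#' Evaluate a quality function
#'
#' @param g an `ldn_graph`.
#' @param p an `ldn_partition` on `g`.
#' @param spec an [`ldn_qspec`][quality_spec].
#' @return the quality value (a single number).
#' @export
quality <- function(g, p, spec) {
  stopifnot(inherits(p, "ldn_partition"), inherits(spec, "ldn_qspec"))
  if (spec$objective == "modularity") {
    if (g$m <= 0) stop("modularity is undefined on a graph with m = 0")
    sum(2 * p$E - spec$gamma * p$K^2 / (2 * g$m)) / (2 * g$m)
  } else {
    sum(p$E - spec$gamma * p$nsize * (p$nsize - 1) / 2)
  }
}

#' Quality scaled by twice the edge weight
#'
#' Reports `quality / (2m)`, the scale on which benchmark results are
#' conventionally plotted for CPM.
#'
#' @inheritParams quality
#' @export
scaled_quality <- function(g, p, spec) quality(g, p, spec) / (2 * g$m)

# weight from node v to community `target` (and to its own community),
# self-loops excluded (they cancel in all deltas)
weight_to_comms <- function(g, p, v, targets) {
  r <- nbr_range(g, v)
  if (!length(r)) return(numeric(length(targets)))
  cc <- p$memb[g$nbr[r]]
  w <- g$wt[r]
  vapply(targets, function(t) sum(w[cc == t]), numeric(1))
}

#' Quality change of moving one node
#'
#' Exact change in the quality function if node `v` is moved from its current
#' community to `target`, computed in `O(deg v)` from the cached aggregates.
#' `target = 0` denotes a fresh empty community.
#'
#' @param g an `ldn_graph`.
#' @param p an `ldn_partition`.
#' @param v node id.
#' @param target community id in `1..C`, or `0` for a fresh community.
#' @param spec an `ldn_qspec`.
#' @return the quality difference `quality(after) - quality(before)`.
#' @export
delta_move <- function(g, p, v, target, spec) {
  v <- as.integer(v); target <- as.integer(target)
  if (v < 1L || v > g$n) stop("node id out of range")
  if (target < 0L || target > p$C) stop("target community out of range")
  cv <- p$memb[v]
  if (target == cv) return(0)
  gam <- gamma_eff(g, spec)
  mv <- node_mass(g, spec)[v]
  A <- comm_mass(p, spec)
  w <- weight_to_comms(g, p, v, c(cv, target))
  s_old <- w[1L] - gam * mv * (A[cv] - mv)
  s_new <- if (target == 0L) 0 else w[2L] - gam * mv * A[target]
  delta_scale(g, spec) * (s_new - s_old)
}

# total edge weight between two communities
inter_weight <- function(g, p, c1, c2) {
  e <- g$edges
  ci <- p$memb[e$i]; cj <- p$memb[e$j]
  sum(e$w[(ci == c1 & cj == c2) | (ci == c2 & cj == c1)])
}

#' Quality change of merging two communities
#'
#' @param g an `ldn_graph`.
#' @param p an `ldn_partition`.
#' @param c1,c2 distinct community ids.
#' @param spec an `ldn_qspec`.
#' @return the quality difference if `c1` and `c2` are fused.
#' @export
delta_merge <- function(g, p, c1, c2, spec) {
  c1 <- as.integer(c1); c2 <- as.integer(c2)
  if (c1 == c2) stop("cannot merge a community with itself")
  if (min(c1, c2) < 1L || max(c1, c2) > p$C) stop("community id out of range")
  E12 <- inter_weight(g, p, c1, c2)
  if (spec$objective == "modularity") {
    (2 * E12 - 2 * spec$gamma * p$K[c1] * p$K[c2] / (2 * g$m)) / (2 * g$m)
  } else {
    E12 - spec$gamma * p$nsize[c1] * p$nsize[c2]
  }
}

#' @export
print.ldn_partition <- function(x, ...) {
  cat(sprintf("ldn_partition: %d nodes in %d communities (sizes: %s)\n",
              length(x$memb), x$C,
              paste(head(sort(x$csize, decreasing = TRUE), 10L), collapse = ", ")))
  invisible(x)
}

#' @export
print.ldn_qspec <- function(x, ...) {
  cat(sprintf("quality spec: %s, gamma = %g\n", x$objective, x$gamma))
  invisible(x)
}
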