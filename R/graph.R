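#' @useDynLib leidenr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif
#' @importFrom utils head
NULL

#' Build an undirected weighted graph from an edge list
#'
#' Nodes are relabelled to contiguous integers in order of first appearance;
#' the original labels are retained for output. Duplicate `(u, v)` entries have
#' their weights summed. A self-loop of weight `w` contributes `2w` to the
#' strength of its node and `w` to the total edge weight `m` -- the unique
#' convention under which aggregation preserves both quality functions exactly.
#'
#' @param from,to endpoint vectors (character labels or positive integers).
#' @param weight positive edge weights; defaults to 1 for every edge.
#' @param n number of nodes; defaults to the largest id seen (integer input
#'   only). Allows isolated trailing nodes.
#' @param labels character labels per node; derived from `from`/`to` when those
#'   are character.
#' @param node_sizes positive node sizes used by CPM; default 1 per node.
#' @param strength optional per-node strength override (used by aggregation and
#'   by scale-preserving subgraphs); computed from the edges when `NULL`.
#' @param m optional total-edge-weight override; computed when `NULL`.
#' @return an object of class `ldn_graph` with fields `n`, `size`, `strength`,
#'   `m`, `selfw`, CSR adjacency (`indptr`, `nbr`, `wt`, all over non-loop
#'   edges), the deduplicated edge table `edges` (`i`, `j`, `w`, each
#'   undirected edge once, self-loops included) and `labels`.
#' @export
graph_from_edges <- function(from, to, weight = NULL, n = NULL, labels = NULL,
                             node_sizes = NULL, strength = NULL, m = NULL) {
  if (length(from) != length(to))
    stop("`from` and `to` must have the same length")
  ne <- length(from)
  if (is.null(weight)) weight <- rep(1, ne)
  weight <- as.numeric(weight)
  if (length(weight) != ne) stop("`weight` must match the number of edges")
  if (ne > 0 && (anyNA(weight) || any(weight <= 0)))
    stop("all edge weights must be strictly positive")

  if (is.character(from) || is.character(to) || is.factor(from)) {
    from <- as.character(from); to <- as.character(to)
    labs <- unique(as.vector(rbind(from, to)))  # first-appearance order
    if (!is.null(labels)) {
      if (!all(labs %in% labels)) stop("`labels` must contain every endpoint")
      labs <- labels
    }
    i <- match(from, labs); j <- match(to, labs)
    if (is.null(n)) n <- length(labs)
  } else {
    i <- as.integer(from); j <- as.integer(to)
    if (ne > 0 && (anyNA(i) || anyNA(j) || any(i < 1L) || any(j < 1L)))
      stop("integer node ids must be positive")
    if (is.null(n)) n <- if (ne > 0) max(i, j) else 0L
    labs <- if (is.null(labels)) as.character(seq_len(n)) else labels
  }
  n <- as.integer(n)
  if (n < 1L) stop("graph must have at least one node")
  if (length(labs) != n) stop("`labels` must have length n")
  if (ne > 0 && max(i, j) > n) stop("edge endpoint exceeds n")

  if (is.null(node_sizes)) node_sizes <- rep(1, n)
  node_sizes <- as.numeric(node_sizes)
  if (length(node_sizes) != n || any(node_sizes <= 0))
    stop("node sizes must be strictly positive, one per node")

  # canonicalize and merge duplicates
  if (ne > 0) {
    u <- pmin(i, j); v <- pmax(i, j)
    key <- (as.numeric(u) - 1) * n + as.numeric(v)
    agg <- rowsum(weight, group = key)
    kk <- as.numeric(rownames(agg))
    u2 <- as.integer((kk - 1) %/% n + 1)
    v2 <- as.integer(kk - (as.numeric(u2) - 1) * n)
    w2 <- as.numeric(agg[, 1L])
  } else {
    u2 <- integer(0); v2 <- integer(0); w2 <- numeric(0)
  }

  loop <- u2 == v2
  selfw <- numeric(n)
  selfw[u2[loop]] <- w2[loop]

  src <- c(u2[!loop], v2[!loop])
  dst <- c(v2[!loop], u2[!loop])
  ww  <- rep(w2[!loop], 2L)
  deg <- tabulate(src, nbins = n)
  o <- order(src, dst)
  indptr <- c(0L, cumsum(deg))

  str_computed <- numeric(n)
  if (length(src)) {
    s <- rowsum(ww, group = src)
    str_computed[as.integer(rownames(s))] <- s[, 1L]
  }
  str_computed <- str_computed + 2 * selfw

  g <- structure(list(
    n = n,
    size = node_sizes,
    strength = if (is.null(strength)) str_computed else as.numeric(strength),
    m = if (is.null(m)) sum(w2) else as.numeric(m),
    selfw = selfw,
    indptr = indptr,
    nbr = dst[o],
    wt = ww[o],
    edges = list(i = u2, j = v2, w = w2),
    labels = as.character(labs)
  ), class = "ldn_graph")
  g
}

#' Read a whitespace-separated edge list
#'
#' Lines hold `u v` or `u v w`; `#`-prefixed lines and blank lines are ignored.
#' Node ids are arbitrary strings, mapped to contiguous integers in
#' first-appearance order; the label map is kept on the graph for round-trip
#' output. Duplicate edges have their weights summed.
#'
#' @param path path to the edge-list file.
#' @param weighted `TRUE` to require a third weight column, `FALSE` to forbid
#'   it, `NA` (default) to accept either.
#' @return an [`ldn_graph`][graph_from_edges] object.
#' @export
read_edge_list <- function(path, weighted = NA) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("edge list contains no edges: ", path)
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  nt <- lengths(toks)
  bad <- which(nt < 2L | nt > 3L)
  if (length(bad))
    stop(sprintf("malformed edge-list line %d: '%s'", idx[bad[1L]], lines[idx[bad[1L]]]))
  if (isTRUE(weighted) && any(nt != 3L)) {
    b <- idx[which(nt != 3L)[1L]]
    stop(sprintf("line %d has no weight but weighted = TRUE", b))
  }
  if (isFALSE(weighted) && any(nt == 3L)) {
    b <- idx[which(nt == 3L)[1L]]
    stop(sprintf("line %d has a weight but weighted = FALSE", b))
  }
  u <- vapply(toks, `[[`, "", 1L)
  v <- vapply(toks, `[[`, "", 2L)
  w <- rep(1, length(toks))
  has_w <- nt == 3L
  if (any(has_w)) {
    wr <- suppressWarnings(as.numeric(vapply(toks[has_w], `[[`, "", 3L)))
    if (anyNA(wr)) {
      b <- idx[has_w][which(is.na(wr))[1L]]
      stop(sprintf("line %d: weight does not parse as a number", b))
    }
    if (any(wr <= 0)) {
      b <- idx[has_w][which(wr <= 0)[1L]]
      stop(sprintf("line %d: edge weight must be strictly positive", b))
    }
    w[has_w] <- wr
  }
  graph_from_edges(u, v, weight = w)
}

#' Write an edge list
#'
#' Inverse of [read_edge_list()]: one line per undirected edge (self-loops
#' included), original node labels, weight column included when any weight
#' differs from 1.
#'
#' @param g an `ldn_graph`.
#' @param path output path.
#' @export
write_edge_list <- function(g, path) {
  e <- g$edges
  if (all(e$w == 1)) {
    lines <- paste(g$labels[e$i], g$labels[e$j])
  } else {
    lines <- paste(g$labels[e$i], g$labels[e$j], format(e$w, digits = 15, trim = TRUE))
  }
  writeLines(lines, path)
  invisible(path)
}

nbr_range <- function(g, v) {
  if (g$indptr[v] == g$indptr[v + 1L]) return(integer(0))
  seq.int(g$indptr[v] + 1L, g$indptr[v + 1L])
}

#' Connected components of a graph
#'
#' Breadth-first search over the adjacency; components are returned in order of
#' their smallest member id.
#'
#' @param g an `ldn_graph`.
#' @return a list of integer node-id vectors partitioning `1:n`.
#' @export
graph_components <- function(g) {
  comp <- component_ids(g)
  unname(split(seq_len(g$n), comp))
}

component_ids <- function(g, nodes = NULL) {
  n <- g$n
  active <- if (is.null(nodes)) rep(TRUE, n) else {
    a <- rep(FALSE, n); a[nodes] <- TRUE; a
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!active[s] || comp[s] != 0L) next
    cur <- cur + 1L
    comp[s] <- cur
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      nb <- g$nbr[nbr_range(g, v)]
      nb <- nb[active[nb] & comp[nb] == 0L]
      if (length(nb)) {
        comp[nb] <- cur
        stack <- c(stack, nb)
      }
    }
  }
  if (is.null(nodes)) comp else comp[nodes]
}

#' Induced subgraph
#'
#' Keeps only edges with both endpoints inside `nodes`. With
#' `keep_scale = TRUE` the subgraph retains the parent graph's per-node
#' strengths and total edge weight `m`, so that modularity evaluated on the
#' subgraph is consistent with modularity on the full graph (the configuration
#' null model keeps its global scale); CPM needs no such adjustment.
#'
#' @param g an `ldn_graph`.
#' @param nodes nonempty vector of node ids (1-based).
#' @param keep_scale retain parent strengths and `m` (default `FALSE`).
#' @return a list with `graph` (the subgraph) and `ids` (for each subgraph
#'   node, its id in `g`).
#' @export
induced_subgraph <- function(g, nodes, keep_scale = FALSE) {
  nodes <- sort(unique(as.integer(nodes)))
  if (!length(nodes)) stop("`nodes` must be a nonempty node set")
  if (any(nodes < 1L | nodes > g$n)) stop("node id out of range")
  inset <- rep(FALSE, g$n)
  inset[nodes] <- TRUE
  e <- g$edges
  keep <- inset[e$i] & inset[e$j]
  map <- integer(g$n)
  map[nodes] <- seq_along(nodes)
  sub <- graph_from_edges(
    map[e$i[keep]], map[e$j[keep]], weight = e$w[keep],
    n = length(nodes), labels = g$labels[nodes],
    node_sizes = g$size[nodes],
    strength = if (keep_scale) g$strength[nodes] else NULL,
    m = if (keep_scale) g$m else NULL
  )
  list(graph = sub, ids = nodes)
}

#' Aggregate a graph by a partition
#'
#' Each community becomes one aggregate node whose size is the summed member
#' size and whose strength is the summed member strength; the internal weight
#' of a community becomes a self-loop, inter-community weights become edges,
#' and the total edge weight `m` is preserved exactly. Evaluating either
#' quality function on the aggregate (with the induced partition) reproduces
#' the value on the original graph.
#'
#' @param g an `ldn_graph`.
#' @param p an [`ldn_partition`][partition] on `g`.
#' @return a list with `graph` (the aggregate, one node per community) and
#'   `map` (community id of each original node, equal to `p$memb`).
#' @export
aggregate_graph <- function(g, p) {
  stopifnot(inherits(p, "ldn_partition"), length(p$memb) == g$n)
  cl <- p$memb
  e <- g$edges
  agg <- graph_from_edges(
    cl[e$i], cl[e$j], weight = e$w, n = p$C,
    labels = paste0("c", seq_len(p$C)),
    node_sizes = p$nsize, strength = p$K, m = g$m
  )
  list(graph = agg, map = cl)
}

#' @export
print.ldn_graph <- function(x, ...) {
  cat(sprintf("ldn_graph: %d nodes, %d edges (m = %g, %d self-loops)\n",
              x$n, length(x$edges$w), x$m, sum(x$edges$i == x$edges$j)))
  invisible(x)
}
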