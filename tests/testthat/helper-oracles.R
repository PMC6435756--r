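# Independent oracles and fixture builders used across the suite.

# From-scratch quality: recomputes every per-community term directly from the
# edge table and membership vector, independent of the cached aggregates in
# ldn_partition.
quality_oracle <- function(g, memb, spec) {
  memb <- as.integer(memb)
  e <- g$edges
  comms <- sort(unique(memb))
  E <- vapply(comms, function(c) sum(e$w[memb[e$i] == c & memb[e$j] == c]), numeric(1))
  K <- vapply(comms, function(c) sum(g$strength[memb == c]), numeric(1))
  nn <- vapply(comms, function(c) sum(g$size[memb == c]), numeric(1))
  if (spec$objective == "modularity")
    sum(2 * E - spec$gamma * K^2 / (2 * g$m)) / (2 * g$m)
  else
    sum(E - spec$gamma * nn * (nn - 1) / 2)
}

# Erdos-Renyi-style random graph; guarantees at least one edge.
rand_graph <- function(n, p = 0.1, weighted = FALSE) {
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  i <- pairs[keep, 1L]; j <- pairs[keep, 2L]
  if (!length(i)) { i <- 1L; j <- 2L }
  w <- if (weighted) runif(length(i), 0.5, 2) else rep(1, length(i))
  graph_from_edges(i, j, weight = w, n = n)
}

rand_membership <- function(n, C = max(2L, n %/% 3L)) {
  sample.int(C, n, replace = TRUE)
}

# All set partitions of 1..n as restricted-growth membership vectors.
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxl) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (l in seq_len(maxl + 1L)) rec(c(prefix, l), max(maxl, l))
  }
  rec(integer(0), 0L)
  out
}

# Global optimum by exhaustive enumeration (n <= 8 in practice).
best_partition_bruteforce <- function(g, spec) {
  parts <- enumerate_partitions(g$n)
  qs <- vapply(parts, function(m) quality_oracle(g, m, spec), numeric(1))
  list(quality = max(qs), membership = parts[[which.max(qs)]])
}

# Brute-force pair-counting Rand statistics on small partitions.
ari_oracle <- function(a, b) {
  n <- length(a)
  s_both <- s_a <- s_b <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pa <- a[i] == a[j]; pb <- b[i] == b[j]
    s_a <- s_a + pa; s_b <- s_b + pb; s_both <- s_both + (pa && pb)
  }
  np <- n * (n - 1) / 2
  expected <- s_a * s_b / np
  denom <- (s_a + s_b) / 2 - expected
  if (denom == 0) 1 else (s_both - expected) / denom
}

two_triangles <- function() {
  graph_from_edges(c("a", "b", "c", "d", "e", "f"),
                   c("b", "c", "a", "e", "f", "d"))
}

# Two 4-cliques (edge weight 3) joined by one weak bridge (weight 0.5):
# under CPM gamma = 0.5 the optimal subpartition is the two cliques.
two_cliques_bridged <- function() {
  cl1 <- utils::combn(1:4, 2L)
  cl2 <- utils::combn(5:8, 2L)
  graph_from_edges(c(cl1[1, ], cl2[1, ], 4L), c(cl1[2, ], cl2[2, ], 5L),
                   weight = c(rep(3, 12), 0.5), n = 8L)
}

edge_file <- function(lines) {
  f <- tempfile(fileext = ".edges")
  writeLines(lines, f)
  f
}
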