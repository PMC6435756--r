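#' Planted-partition benchmark specification
#'
#' Equal-size communities; edges are placed one at a time: with probability
#' `mu` an edge falls between two (distinct, uniformly chosen) communities,
#' otherwise inside a uniformly chosen community; endpoints are uniform within
#' their community, and self-loops and duplicate edges are rejected and
#' resampled. The total number of edges is `round(n * avg_degree / 2)`.
#'
#' @param n number of nodes (divisible by `community_size`).
#' @param community_size nodes per community (>= 2). Default 50.
#' @param avg_degree target average degree (`< n - 1`). Default 10.
#' @param mu mixing parameter in `[0, 1)`: probability that an edge falls
#'   between communities.
#' @param seed integer seed; the generator is deterministic per spec + seed.
#' @return an object of class `ldn_benchspec`.
#' @export
benchmark_spec <- function(n, community_size = 50L, avg_degree = 10,
                           mu = 0.1, seed = 1L) {
  n <- as.integer(n); community_size <- as.integer(community_size)
  if (community_size < 2L) stop("`community_size` must be at least 2")
  if (n < 2L * community_size) stop("`n` must be at least two communities")
  if (n %% community_size != 0L) stop("`n` must be divisible by `community_size`")
  if (avg_degree >= n - 1) stop("`avg_degree` must be below n - 1")
  if (mu < 0 || mu >= 1) stop("`mu` must be in [0, 1)")
  structure(list(n = n, community_size = community_size,
                 avg_degree = avg_degree, mu = mu, seed = as.integer(seed)),
            class = "ldn_benchspec")
}

#' Generate a planted-partition benchmark network
#'
#' @param bspec an [`ldn_benchspec`][benchmark_spec].
#' @return a list with `graph` (an `ldn_graph` with exactly
#'   `round(n * avg_degree / 2)` distinct edges), `planted` (the equal-size
#'   `ldn_partition`), and `realized` (realized mean degree and
#'   inter-community edge fraction). The caller's RNG state is restored.
#' @export
generate_benchmark <- function(bspec) {
  stopifnot(inherits(bspec, "ldn_benchspec"))
  n <- bspec$n; cs <- bspec$community_size
  ncomm <- n %/% cs
  M <- round(n * bspec$avg_degree / 2)
  if (M > n * (n - 1) / 2) stop("requested edge count exceeds graph capacity")
  comm <- rep(seq_len(ncomm), each = cs)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(bspec$seed)

  # number of inter-community edges first (each edge is inter with
  # probability mu), then distinct edges of each type by rejection; this
  # keeps the realized inter fraction exactly binomial, undistorted by the
  # higher collision rate of the much smaller intra-community pair pool
  n_inter <- stats::rbinom(1L, M, bspec$mu)
  n_intra <- M - n_inter
  if (n_intra > ncomm * cs * (cs - 1) / 2)
    stop("requested intra-community edges exceed capacity")

  draw_distinct <- function(need, propose) {
    keys <- numeric(0)
    ei <- integer(0); ej <- integer(0)
    attempts <- 0L
    while (length(keys) < need) {
      prop <- propose(max(2L * (need - length(keys)), 64L))
      a <- pmin(prop$u, prop$v); b <- pmax(prop$u, prop$v)
      key <- (as.numeric(a) - 1) * n + b
      ok <- !duplicated(key) & !(key %in% keys)
      if (any(ok)) {
        take <- which(ok)[seq_len(min(need - length(keys), sum(ok)))]
        keys <- c(keys, key[take])
        ei <- c(ei, a[take]); ej <- c(ej, b[take])
      }
      attempts <- attempts + 1L
      if (attempts > 1000L)
        stop("could not place the requested number of distinct edges")
    }
    list(i = ei, j = ej)
  }

  inter <- draw_distinct(n_inter, function(nb) {
    c1 <- sample.int(ncomm, nb, replace = TRUE)   # two distinct communities
    c2 <- sample.int(ncomm - 1L, nb, replace = TRUE)
    c2 <- c2 + (c2 >= c1)
    list(u = (c1 - 1L) * cs + sample.int(cs, nb, replace = TRUE),
         v = (c2 - 1L) * cs + sample.int(cs, nb, replace = TRUE))
  })
  intra <- draw_distinct(n_intra, function(nb) {
    c0 <- sample.int(ncomm, nb, replace = TRUE)   # two distinct nodes inside
    o1 <- sample.int(cs, nb, replace = TRUE)
    o2 <- sample.int(cs - 1L, nb, replace = TRUE)
    o2 <- o2 + (o2 >= o1)
    list(u = (c0 - 1L) * cs + o1, v = (c0 - 1L) * cs + o2)
  })

  g <- graph_from_edges(c(inter$i, intra$i), c(inter$j, intra$j), n = n)
  list(
    graph = g,
    planted = partition(g, comm),
    realized = list(
      mean_degree = 2 * M / n,
      inter_fraction = n_inter / M
    )
  )
}

#' Resolution parameter from the mixing parameter
#'
#' Under CPM the resolution acts as a density threshold: planted communities
#' should be denser than `gamma`, the space between them sparser. With
#' expected intra-community density
#' `p_in = (1 - mu) * avg_degree / (community_size - 1)` and inter-community
#' density `p_out = mu * avg_degree / (n - community_size)` typically orders
#' of magnitude apart, the returned value is their geometric mean
#' `sqrt(p_in * p_out)` -- the midpoint of the admissible interval on a log
#' scale, equidistant from both densities in ratio terms. This maximizes the
#' margin against both failure modes simultaneously: splitting a planted
#' community (profitable when `gamma` approaches `p_in`) and merging two of
#' them (profitable when `gamma` approaches `p_out`). The arithmetic midpoint
#' sits so close to `p_in` on sparse benchmarks that density fluctuations
#' make splitting planted communities strictly profitable, and even an exact
#' CPM optimizer then returns a finer partition than the planted one.
#'
#' For `mu = 0` (no expected inter-community edges, `p_out = 0`) any
#' `gamma` in `(0, p_in)` detects the partition and `p_in / 2` is returned.
#' When `p_in <= p_out` the planted partition is undetectable by density and
#' a warning is raised (the returned value carries
#' `attr(, "detectable") = FALSE`).
#'
#' @param bspec an `ldn_benchspec`.
#' @return the resolution `gamma` (a positive number).
#' @export
resolution_from_mu <- function(bspec) {
  stopifnot(inherits(bspec, "ldn_benchspec"))
  p_in <- (1 - bspec$mu) * bspec$avg_degree / (bspec$community_size - 1)
  p_out <- bspec$mu * bspec$avg_degree / (bspec$n - bspec$community_size)
  gamma <- if (p_out == 0) p_in / 2 else sqrt(p_in * p_out)
  detectable <- p_in > p_out
  if (!detectable)
    warning("expected intra-community density does not exceed inter-community density; the planted partition is undetectable")
  structure(gamma, detectable = detectable)
}

contingency <- function(a, b) {
  table(factor(a), factor(b))
}

#' Compare a found partition with the planted one
#'
#' `exact_match` is equality up to a relabelling of communities; `ari` is the
#' adjusted Rand index (pair counting, corrected for chance) and `nmi` the
#' normalized mutual information (normalized by the arithmetic mean of the two
#' entropies).
#'
#' @param found,planted `ldn_partition`s (or plain membership vectors) over
#'   the same nodes.
#' @return a list with `exact_match`, `ari`, `nmi`.
#' @export
score_recovery <- function(found, planted) {
  a <- if (inherits(found, "ldn_partition")) found$memb else as.integer(found)
  b <- if (inherits(planted, "ldn_partition")) planted$memb else as.integer(planted)
  if (length(a) != length(b)) stop("partitions must cover the same nodes")
  n <- length(a)
  tab <- contingency(a, b)
  nij <- as.numeric(tab)
  ai <- rowSums(tab); bj <- colSums(tab)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(nij)); sum_a <- sum(ch2(ai)); sum_b <- sum(ch2(bj))
  expected <- sum_a * sum_b / ch2(n)
  denom <- (sum_a + sum_b) / 2 - expected
  ari <- if (denom == 0) 1 else (sum_ij - expected) / denom
  pij <- nij / n; pa <- ai / n; pb <- bj / n
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pe <- outer(pa, pb)
  mi <- sum(ifelse(pij > 0, pij * log(pij / as.numeric(pe)), 0))
  hh <- (H(pa) + H(pb)) / 2
  nmi <- if (hh == 0) 1 else mi / hh
  list(
    exact_match = same_partition(a, b),
    ari = ari,
    nmi = nmi
  )
}

#' Bridge fixture: a graph on which Louvain disconnects a community
#'
#' Builds a hub node `"0"` bridging two internally tied triads (`"1"`-`"3"`
#' and `"4"`-`"6"`), plus an external community of `n_satellites` strongly
#' interconnected nodes that attracts the hub through many connections. Under
#' CPM with `gamma = 1`, moving the hub to the external community is a
#' strictly improving move, after which each triad node's best single move is
#' to stay -- so greedy local moving leaves the former hub community
#' internally disconnected. These three properties are certified at
#' construction time via [delta_move()] and component counts; construction
#' fails if any certification fails.
#'
#' @param n_satellites number of external-community nodes (>= 2). Default 5.
#' @param seed integer seed (kept for interface symmetry; the certified
#'   weights are deterministic).
#' @return a list with `graph`, `start` (the adversarial pre-move
#'   `ldn_partition`: hub + both triads together, external community
#'   separate), `spec` (CPM, `gamma = 1`), `hub` (node id of `"0"`) and
#'   `triads` (node ids of the two triads).
#' @export
make_bridge_fixture <- function(n_satellites = 5L, seed = 1L) {
  n_satellites <- as.integer(n_satellites)
  if (n_satellites < 2L) stop("`n_satellites` must be at least 2")
  b <- 5   # intra-triad weight
  a <- 2   # hub-triad bridge weight
  cw <- 3  # hub-satellite weight
  d <- 5   # satellite clique weight
  sat <- paste0("x", seq_len(n_satellites))
  from <- c("0", "0",
            "1", "2", "1",
            "4", "5", "4")
  to <- c("1", "4",
          "2", "3", "3",
          "5", "6", "6")
  w <- c(a, a, b, b, b, b, b, b)
  from <- c(from, rep("0", n_satellites)); to <- c(to, sat)
  w <- c(w, rep(cw, n_satellites))
  if (n_satellites > 1L) {
    pairs <- utils::combn(sat, 2L)
    from <- c(from, pairs[1L, ]); to <- c(to, pairs[2L, ])
    w <- c(w, rep(d, ncol(pairs)))
  }
  g <- graph_from_edges(from, to, weight = w)
  spec <- quality_spec("cpm", gamma = 1)
  hub <- match("0", g$labels)
  triads <- list(match(as.character(1:3), g$labels),
                 match(as.character(4:6), g$labels))
  ext <- match(sat, g$labels)
  memb <- integer(g$n)
  memb[c(hub, triads[[1L]], triads[[2L]])] <- 1L
  memb[ext] <- 2L
  start <- partition(g, memb)

  # certification
  red <- start$memb[hub]
  xc <- start$memb[ext[1L]]
  if (delta_move(g, start, hub, xc, spec) <= 0)
    stop("bridge fixture certification failed: hub move is not improving")
  after <- partition(g, replace(start$memb, hub, xc))
  redc <- after$memb[triads[[1L]][1L]]
  for (v in c(triads[[1L]], triads[[2L]])) {
    best <- max(vapply(c(0L, setdiff(seq_len(after$C), after$memb[v])),
                       function(t) delta_move(g, after, v, t, spec), numeric(1)))
    if (best > 0)
      stop("bridge fixture certification failed: a triad node can improve by moving")
  }
  redmembers <- which(after$memb == redc)
  if (max(component_ids(g, redmembers)) != 2L)
    stop("bridge fixture certification failed: hub community does not split into 2 components")

  list(graph = g, start = start, spec = spec, hub = hub, triads = triads)
}
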