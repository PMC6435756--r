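test_that("gamma-separation detects mergeable community pairs", {
  edgeless <- graph_from_edges(integer(0), integer(0), n = 4)
  expect_true(is_gamma_separated(edgeless, singleton_partition(edgeless),
                                 quality_spec("cpm", 1)))

  # two 3-cliques joined by edges denser than gamma, kept separate
  cl <- utils::combn(1:3, 2)
  g <- graph_from_edges(c(cl[1, ], cl[1, ] + 3L, 1, 2, 3),
                        c(cl[2, ], cl[2, ] + 3L, 4, 5, 6), n = 6)
  p <- partition(g, c(1, 1, 1, 2, 2, 2))
  spec_lo <- quality_spec("cpm", 0.1)   # inter-density 3/9 > 0.1: merge pays
  expect_gt(delta_merge(g, p, 1L, 2L, spec_lo), 0)
  expect_false(is_gamma_separated(g, p, spec_lo))
  spec_hi <- quality_spec("cpm", 0.9)
  expect_true(is_gamma_separated(g, p, spec_hi))
})

test_that("connectivity checker flags communities without internal paths", {
  g <- graph_from_edges(c(1, 3), c(2, 4), n = 4)
  expect_true(is_connected_partition(g, singleton_partition(g)))
  expect_true(is_connected_partition(g, partition(g, c(1, 1, 2, 2))))
  expect_false(is_connected_partition(g, partition(g, c(1, 2, 1, 2))))
})

test_that("node-optimality checker spots a misassigned node", {
  g <- two_triangles()
  spec <- quality_spec("cpm", 0.5)
  expect_true(is_node_optimal(g, partition(g, c(1, 1, 1, 2, 2, 2)), spec))
  expect_false(is_node_optimal(g, partition(g, c(1, 1, 2, 2, 2, 2)), spec))
})

test_that("subpartition gamma-density follows the recursive definition", {
  spec <- quality_spec("cpm", 0.5)
  # singleton community
  g1 <- graph_from_edges(1, 2, n = 2)
  expect_true(is_subpartition_gamma_dense(g1, singleton_partition(g1), spec, 1L))
  # clique at gamma below its internal density: dense
  cl <- utils::combn(1:5, 2)
  clique <- graph_from_edges(cl[1, ], cl[2, ], n = 5)
  expect_true(is_subpartition_gamma_dense(clique, partition(clique, rep(1, 5)), spec, 1L))
  # two cliques joined by one weak edge at high gamma: the joining cut fails
  g2 <- two_cliques_bridged()
  expect_false(is_subpartition_gamma_dense(g2, partition(g2, rep(1, 8)),
                                           quality_spec("cpm", 2), 1L))
  # too-large community is "not checkable", distinct from FALSE
  big <- graph_from_edges(1:19, c(2:19, 1), n = 19)
  expect_true(is.na(is_subpartition_gamma_dense(big, partition(big, rep(1, 19)),
                                                spec, 1L, max_exhaustive = 12L)))
})

test_that("uniform gamma-density fails on disconnected communities and low cuts", {
  spec <- quality_spec("cpm", 0.5)
  g <- graph_from_edges(c(1, 3), c(2, 4), n = 4)
  expect_true(is_uniformly_gamma_dense(g, partition(g, c(1, 1, 2, 2)), spec, 1L))
  disc <- partition(g, c(1, 2, 1, 2))
  expect_false(is_uniformly_gamma_dense(g, disc, spec, 1L))   # zero cut inside
  cl <- utils::combn(1:4, 2)
  clique <- graph_from_edges(cl[1, ], cl[2, ], n = 4)
  expect_true(is_uniformly_gamma_dense(clique, partition(clique, rep(1, 4)),
                                       quality_spec("cpm", 1), 1L))
})

test_that("subset optimality implies uniform gamma-density on random converged runs", {
  set.seed(300)
  checked <- 0L
  for (rep in 1:15) {
    g <- rand_graph(sample(5:9, 1), runif(1, 0.3, 0.7))
    spec <- quality_spec("cpm", runif(1, 0.2, 0.8))
    run <- leiden(g, spec, leiden_config(seed = rep, max_iterations = 30,
                                         stop_policy = "until_converged"))
    for (c in seq_len(run$partition$C)) {
      so <- is_subset_optimal(g, run$partition, spec, c)
      expect_true(so)
      if (isTRUE(so)) {
        expect_true(is_uniformly_gamma_dense(g, run$partition, spec, c))
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 10L)
})

test_that("the audit classifies disjoint cliques as clean", {
  cl <- utils::combn(1:4, 2)
  g <- graph_from_edges(c(cl[1, ], cl[1, ] + 4L), c(cl[2, ], cl[2, ] + 4L), n = 8)
  p <- partition(g, rep(1:2, each = 4))
  audit <- audit_partition(g, p, quality_spec("modularity", 1))
  expect_equal(audit$pct_disconnected, 0)
  expect_equal(audit$pct_badly_connected, 0)
  expect_true(all(audit$per_community$n_subcommunities == 1L))
})

test_that("the audit counts the post-move bridge community as disconnected, with a split gain", {
  fix <- make_bridge_fixture()
  moved <- fix$start$memb
  moved[fix$hub] <- setdiff(unique(fix$start$memb), fix$start$memb[fix$hub])[1]
  p <- partition(fix$graph, moved)
  audit <- audit_partition(fix$graph, p, fix$spec)
  pc <- audit$per_community
  expect_true(any(!pc$connected))
  expect_true(all(pc$badly_connected[!pc$connected]))   # disconnected => badly connected
  expect_true(all(pc$split_gain[pc$n_subcommunities > 1L] > 0))
  expect_gte(audit$pct_badly_connected, audit$pct_disconnected)
})

test_that("leiden output audits clean on connectivity under consistent modularity", {
  set.seed(310)
  g <- rand_graph(60, 0.08)
  spec <- quality_spec("modularity", 1)
  run <- leiden(g, spec, leiden_config(seed = 2))
  audit <- audit_partition(g, run$partition, spec)
  expect_equal(audit$pct_disconnected, 0)
  expect_true(all(audit$per_community$split_gain >= 0))
})

test_that("consistent subnetwork modularity uses global scale in the audit", {
  set.seed(320)
  g <- rand_graph(30, 0.2)
  spec <- quality_spec("modularity", 1)
  p <- partition(g, rand_membership(30, 3))
  nodes <- which(p$memb == 1L)
  sub <- induced_subgraph(g, nodes, keep_scale = TRUE)$graph
  # the consistent subnetwork quality of the whole community equals that
  # community's contribution to the full-graph modularity
  contrib <- (2 * p$E[1] - spec$gamma * p$K[1]^2 / (2 * g$m)) / (2 * g$m)
  expect_equal(quality(sub, partition(sub, rep(1L, sub$n)), spec), contrib,
               tolerance = 1e-12)
})
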