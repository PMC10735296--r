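# Leaf ids in build_toy_tree_sequence fixtures follow sorted label order.

test_that("parental node is the first node on the path to the root", {
  ts <- build_toy_tree_sequence(data.frame(newick = "((u,x),y)", span = 10))
  tr <- ts$trees[[1]]
  u <- toy_leaf(ts, "u"); x <- toy_leaf(ts, "x"); y <- toy_leaf(ts, "y")
  v <- parental_node(tr, u)
  expect_identical(v, parental_node(tr, x))   # u and x share a cherry
  expect_false(v == parental_node(tr, y))     # y hangs from the root
  ts2 <- build_toy_tree_sequence(data.frame(newick = "(u,(x,y))", span = 10))
  tr2 <- ts2$trees[[1]]
  # u's parent is the root: the root has no parent itself
  expect_true(is.na(tr2$parent[parental_node(tr2, toy_leaf(ts2, "u")) + 1]))
  # detached leaf has no parental node
  iso <- local_tree(0, 10, c(NA_integer_, 3L, 3L, NA_integer_), leaves = 0:2)
  expect_error(parental_node(iso, 0L), "no parental node")
  expect_error(neighbor_set(iso, 0L), "no parental node")
  expect_error(parental_node(tr, 99L), "not in the tree")
})

test_that("neighbor sets follow the parental-node definition, polytomies included", {
  ts <- build_toy_tree_sequence(data.frame(newick = "((u,x),y)", span = 10))
  u <- toy_leaf(ts, "u")
  expect_identical(neighbor_set(ts$trees[[1]], u), toy_leaf(ts, "x"))
  # sibling subtree with two leaves
  ts2 <- build_toy_tree_sequence(data.frame(newick = "(u,(x,y))", span = 10))
  expect_identical(neighbor_set(ts2$trees[[1]], toy_leaf(ts2, "u")),
                   sort(c(toy_leaf(ts2, "x"), toy_leaf(ts2, "y"))))
  # multifurcating parental node: all other leaf children are neighbors
  ts3 <- build_toy_tree_sequence(data.frame(newick = "((u,x,y),z)", span = 10))
  expect_identical(neighbor_set(ts3$trees[[1]], toy_leaf(ts3, "u")),
                   sort(c(toy_leaf(ts3, "x"), toy_leaf(ts3, "y"))))
  # the focal leaf is never its own neighbor
  for (leaf in ts3$samples$leaf_id) {
    expect_false(leaf %in% neighbor_set(ts3$trees[[1]], leaf))
  }
})

test_that("the indicator is 1 exactly for members of the neighbor set", {
  ts <- build_toy_tree_sequence(data.frame(newick = "((u,x),y)", span = 10))
  tr <- ts$trees[[1]]
  u <- toy_leaf(ts, "u")
  expect_identical(indicator(tr, u, toy_leaf(ts, "x")), 1L)
  expect_identical(indicator(tr, u, toy_leaf(ts, "y")), 0L)
  expect_error(indicator(tr, u, u), "must differ")
})

test_that("the 30/70 fixture separates span weighting from tree fractions", {
  ts <- toy_30_70()
  u <- toy_leaf(ts, "u")
  p <- span_weighted_gnn(ts, u)
  x <- as.character(toy_leaf(ts, "x")); y <- as.character(toy_leaf(ts, "y"))
  expect_identical(unname(p$span_fraction[x]), 0.3)
  expect_identical(unname(p$span_fraction[y]), 0.7)
  g <- tree_fraction_gnn(ts, u)
  expect_identical(unname(g[x]), 0.5)
  expect_identical(unname(g[y]), 0.5)
  # single tree: P equals the indicator
  single <- build_toy_tree_sequence(data.frame(newick = "((u,x),y)", span = 80))
  ps <- span_weighted_gnn(single, toy_leaf(single, "u"))
  for (other in c("x", "y")) {
    expect_identical(
      unname(ps$span_fraction[as.character(toy_leaf(single, other))]),
      as.numeric(indicator(single$trees[[1]], toy_leaf(single, "u"),
                           toy_leaf(single, other))))
  }
  # two trees, neighbor in exactly one -> G = 0.5 by the direct formula
  expect_identical(unname(tree_fraction_gnn(ts, u)[x]), 0.5)
})

test_that("fast profiles agree with the naive oracle on random tree sequences", {
  for (s in 1:25) {
    n_leaves <- sample(2:20, 1)
    ts <- random_tree_sequence(n_leaves, sample(1:50, 1), seed = 1000 + s)
    u <- sample(ts$samples$leaf_id, 1)
    fast <- span_weighted_gnn(ts, u)
    slow <- oracle_gnn_prime(ts, u)
    nm <- names(fast$span_fraction)
    expect_lt(max(abs(fast$span_fraction - slow$span_fraction[nm])), 1e-12)
    expect_lt(max(abs(fast$tree_fraction - slow$tree_fraction[nm])), 1e-12)
    expect_equal(fast$effective_span, slow$effective_span)
    # range invariants
    expect_true(all(fast$span_fraction >= 0 & fast$span_fraction <= 1))
    expect_true(all(fast$tree_fraction >= 0 & fast$tree_fraction <= 1))
    expect_false(as.character(u) %in% nm)
  }
})

test_that("sum of P over leaves equals the span-weighted mean neighbor-set size", {
  for (s in 1:5) {
    ts <- random_tree_sequence(sample(3:12, 1), sample(2:30, 1), seed = 300 + s)
    u <- sample(ts$samples$leaf_id, 1)
    p <- span_weighted_gnn(ts, u)
    sizes <- vapply(seq_len(n_trees(ts)), function(i) {
      length(neighbor_set(ts$trees[[i]], u))
    }, numeric(1))
    spans <- vapply(ts$trees, tree_span, numeric(1))
    expect_equal(sum(p$span_fraction), sum(sizes * spans) / sum(spans),
                 tolerance = 1e-12)
    expect_gte(sum(p$span_fraction), 1 - 1e-12)
  }
  # equality to 1 iff the sibling is a single leaf in every tree
  ts <- toy_30_70()
  expect_equal(sum(span_weighted_gnn(ts, toy_leaf(ts, "u"))$span_fraction), 1)
})

test_that("G and P are invariant to permuting tree order", {
  ts <- random_tree_sequence(8, 15, seed = 99)
  u <- 3L
  base <- span_weighted_gnn(ts, u)
  set.seed(1)
  perm <- sample(n_trees(ts))
  # rebase the permuted trees so intervals tile again (spans preserved)
  spans <- vapply(ts$trees[perm], tree_span, numeric(1))
  breaks <- cumsum(c(0, spans))
  trees <- lapply(seq_along(perm), function(i) {
    t <- ts$trees[[perm[i]]]
    local_tree(breaks[i], breaks[i + 1], t$parent, t$leaves)
  })
  shuffled <- tree_sequence_view(ts$chromosome_id, trees, ts$samples)
  p2 <- span_weighted_gnn(shuffled, u)
  expect_equal(p2$span_fraction, base$span_fraction, tolerance = 1e-12)
  expect_equal(p2$tree_fraction, base$tree_fraction, tolerance = 1e-12)
})

test_that("trees where the focal is detached drop from numerator and denominator", {
  # tree 1 (40 bp): u attached, neighbor x; tree 2 (60 bp): u detached
  t1 <- local_tree(0, 40, c(3L, 3L, 4L, 4L, NA), leaves = 0:2)
  t2 <- local_tree(40, 100, c(NA, 3L, 3L, NA), leaves = 0:2)
  samples <- data.frame(leaf_id = 0:2, name = c("u", "x", "y"))
  ts <- tree_sequence_view("chrD", list(t1, t2), samples)
  p <- span_weighted_gnn(ts, 0L)
  expect_equal(p$total_span, 100)
  expect_equal(p$effective_span, 40)
  expect_identical(unname(p$span_fraction["1"]), 1)   # x neighbor on all attached span
  expect_identical(unname(p$span_fraction["2"]), 0)
  expect_equal(p$n_trees_attached, 1L)
  # oracle agrees on the detached handling
  o <- oracle_gnn_prime(ts, 0L)
  expect_equal(o$span_fraction, p$span_fraction)
  # focal detached everywhere -> error
  t3 <- local_tree(0, 10, c(NA, 3L, 3L, NA), leaves = 0:2)
  ts3 <- tree_sequence_view("chrE", list(t3), samples)
  expect_error(span_weighted_gnn(ts3, 0L), "focal never attached")
  expect_error(oracle_gnn_prime(ts3, 0L), "focal never attached")
})

test_that("genome aggregation is span-weighted, not a mean of chromosomes", {
  mk <- function(chrom, spans, topologies) {
    build_toy_tree_sequence(data.frame(newick = topologies, span = spans),
                            chromosome_id = chrom)
  }
  # equal lengths: P 0.2 and 0.4 -> 0.3
  c1 <- mk("c1", c(20, 80), c("((u,x),y)", "((u,y),x)"))
  c2 <- mk("c2", c(40, 60), c("((u,x),y)", "((u,y),x)"))
  p1 <- span_weighted_gnn(c1, 0L); p2 <- span_weighted_gnn(c2, 0L)
  g <- aggregate_genome(list(p1, p2))
  expect_equal(unname(g$span_fraction["1"]), 0.3)
  # unequal lengths expose the weighting: L=100 with P=0, L=300 with P=0.4
  c3 <- mk("c3", 100, "((u,y),x)")
  c4 <- mk("c4", c(120, 180), c("((u,x),y)", "((u,y),x)"))
  g2 <- aggregate_genome(list(span_weighted_gnn(c3, 0L),
                              span_weighted_gnn(c4, 0L)))
  expect_equal(unname(g2$span_fraction["1"]), 0.3)  # (0 + 120) / 400
  expect_equal(g2$n_trees, 3)
  # duplicated chromosome ids are rejected
  expect_error(aggregate_genome(list(p1, p1)), "duplicated chromosome_id")
})

test_that("aggregation over a partition reproduces the unpartitioned profile", {
  ts <- random_tree_sequence(10, 40, seed = 7)
  u <- 2L
  whole <- span_weighted_gnn(ts, u)
  parts <- split_tree_sequence(ts, 5, seed = 2)
  agg <- aggregate_genome(lapply(parts, function(p) span_weighted_gnn(p, u)))
  expect_identical(agg$span_bp, whole$span_bp)
  expect_equal(agg$span_fraction, whole$span_fraction, tolerance = 1e-15)
  expect_equal(agg$tree_fraction, whole$tree_fraction, tolerance = 1e-15)
  expect_equal(agg$effective_span, whole$effective_span)
})
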