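# Diploid fixtures: leaf names a1,a2,b1,b2,c1,c2,d1,d2 map (sorted) to
# leaf ids 0..7; accessions accA..accD own consecutive pairs.

test_that("a tree where both haplotypes are neighbors contributes its span once", {
  # focal a1's parental node holds b1 AND b2 on the first tree (40 bp),
  # only c1 on the second (60 bp)
  ts <- toy_diploid_ts(data.frame(
    newick = c("((a1,b1,b2),(a2,(c1,(c2,(d1,d2)))))",
               "((a1,c1),(a2,(b1,(b2,(c2,(d1,d2))))))"),
    span = c(40, 60)))
  tab <- toy_accession_table()
  prof <- span_weighted_gnn(ts, 0L)
  ap <- accession_collapse(prof, tab, "accA")
  expect_equal(unname(ap$span_fraction_by_accession["accB"]), 0.4)  # 1 not 2
  expect_equal(unname(ap$span_fraction_by_accession["accC"]), 0.6)
  expect_equal(unname(ap$span_fraction_by_accession["accD"]), 0)
  # focal accession absent from its own neighbor map
  expect_false("accA" %in% names(ap$span_fraction_by_accession))
  expect_true(all(ap$span_fraction_by_accession >= 0 &
                  ap$span_fraction_by_accession <= 1))
})

test_that("union over disjoint spans adds accession-level proportions", {
  # b1 neighbor of a1 on 40% of L, b2 on a disjoint 20% -> accB P = 0.6
  ts <- toy_diploid_ts(data.frame(
    newick = c("((a1,b1),(a2,(b2,(c1,(c2,(d1,d2))))))",
               "((a1,b2),(a2,(b1,(c1,(c2,(d1,d2))))))",
               "((a1,c1),(a2,(b1,(b2,(c2,(d1,d2))))))"),
    span = c(40, 20, 40)))
  ap <- accession_collapse(span_weighted_gnn(ts, 0L),
                           toy_accession_table(), "accA")
  expect_equal(unname(ap$span_fraction_by_accession["accB"]), 0.6)
})

test_that("the focal accession's other haplotype is excluded but its span still counts", {
  # a2 is a1's only neighbor on the first tree: that span yields no
  # reported neighbor yet stays in the denominator
  ts <- toy_diploid_ts(data.frame(
    newick = c("((a1,a2),(b1,(b2,(c1,(c2,(d1,d2))))))",
               "((a1,b1),(a2,(b2,(c1,(c2,(d1,d2))))))"),
    span = c(50, 50)))
  ap <- accession_collapse(span_weighted_gnn(ts, 0L),
                           toy_accession_table(), "accA")
  expect_equal(unname(ap$span_fraction_by_accession["accB"]), 0.5)
  expect_equal(ap$effective_span, 100)
  expect_false("accA" %in% names(ap$span_fraction_by_accession))
})

test_that("accession P for a diploid focal is the mean of its two haplotype profiles", {
  ts <- toy_diploid_ts(data.frame(
    newick = c("((a1,b1),(a2,(b2,(c1,(c2,(d1,d2))))))",
               "((a2,c1),(a1,(b1,(b2,(c2,(d1,d2))))))"),
    span = c(30, 70)))
  tab <- toy_accession_table()
  p1 <- accession_collapse(span_weighted_gnn(ts, 0L), tab, "accA")
  p2 <- accession_collapse(span_weighted_gnn(ts, 1L), tab, "accA")
  both <- accession_collapse(gnn_profiles(ts, focals = 0:1), tab, "accA")
  expect_equal(both$span_fraction_by_accession,
               (p1$span_fraction_by_accession +
                p2$span_fraction_by_accession) / 2)
  expect_equal(both$n_focal_haplotypes, 2L)
})

test_that("collapse equals a brute-force union recount on simulated panels", {
  for (s in 1:3) {
    ts <- random_tree_sequence(8, 25, seed = 800 + s)
    tab <- toy_accession_table()
    u <- 0L
    prof <- span_weighted_gnn(ts, u)
    ap <- accession_collapse(prof, tab, "accA")
    # brute force: per tree, per accession, any-haplotype membership
    spans <- vapply(ts$trees, tree_span, numeric(1))
    for (acc in c("accB", "accC", "accD")) {
      haps <- tab$leaf_id[tab$accession_id == acc]
      num <- 0
      for (i in seq_len(n_trees(ts))) {
        if (any(haps %in% neighbor_set(ts$trees[[i]], u))) {
          num <- num + spans[i]
        }
      }
      expect_equal(unname(ap$span_fraction_by_accession[acc]),
                   num / sum(spans), tolerance = 1e-12)
    }
  }
})

test_that("unmapped leaves fail with the offending id listed", {
  ts <- toy_30_70()
  tab <- accession_table(data.frame(
    accession_id = c("accU", "accX"), leaf_id = 0:1,
    haplotype_index = c(0L, 0L), stringsAsFactors = FALSE))
  expect_error(accession_collapse(span_weighted_gnn(ts, 0L), tab, "accU"),
               "not mapped to an accession: 2")
})

test_that("ranking is descending with lexicographic, flagged ties", {
  ap <- structure(list(
    focal_accession = "f", chromosome_id = "genome",
    span_fraction_by_accession = c(B = 0.3, C = 0.1, A = 0.3),
    tree_fraction_by_accession = c(B = 0.25, C = 0.1, A = 0.35),
    n_focal_haplotypes = 1L, effective_span = 100,
    per_chromosome_closest = NULL), class = "accession_profile")
  top2 <- rank_neighbors(ap, 2)
  expect_equal(top2$accession_id, c("A", "B"))
  expect_true(all(top2$tie))
  # k larger than the table returns the full table
  all3 <- rank_neighbors(ap, 10)
  expect_equal(nrow(all3), 3L)
  expect_equal(all3$accession_id, c("A", "B", "C"))
  expect_false(all3$tie[3])
  expect_error(rank_neighbors(ap, 0), "k >= 1")
})

test_that("per-chromosome closest neighbors report all ties lexicographically", {
  mk <- function(chrom, P) {
    structure(list(focal_accession = "f", chromosome_id = chrom,
                   span_fraction_by_accession = P,
                   tree_fraction_by_accession = P,
                   n_focal_haplotypes = 1L, effective_span = 1,
                   per_chromosome_closest = NULL),
              class = "accession_profile")
  }
  res <- closest_per_chromosome(list(
    chrA = mk("chrA", c(x = 0.5, y = 0.2)),
    chrB = mk("chrB", c(y = 0.4, x = 0.4))))
  expect_equal(res$chrA, "x")
  expect_equal(res$chrB, c("x", "y"))
})

test_that("profiles round-trip through JSON and CSV has one row per neighbor", {
  ts <- toy_diploid_ts(data.frame(
    newick = c("((a1,b1),(a2,(b2,(c1,(c2,(d1,d2))))))",
               "((a1,c1),(a2,(b1,(b2,(c2,(d1,d2))))))"),
    span = c(30, 70)))
  ap <- accession_collapse(span_weighted_gnn(ts, 0L),
                           toy_accession_table(), "accA")
  ap$per_chromosome_closest <- list(toydip = "accC")
  prefix <- tempfile("prof")
  paths <- write_profile(ap, prefix)
  df <- read.csv(paths[["csv"]], comment.char = "#")
  expect_equal(nrow(df), length(ap$span_fraction_by_accession))
  expect_equal(names(df),
               c("focal_accession", "neighbor_accession", "P", "G",
                 "chromosome"))
  # version header present
  expect_match(readLines(paths[["csv"]], n = 1), "argneighbor")
  ap2 <- read_profile(paths[["json"]])
  expect_equal(ap2$span_fraction_by_accession, ap$span_fraction_by_accession)
  expect_equal(ap2$tree_fraction_by_accession, ap$tree_fraction_by_accession)
  expect_equal(ap2$focal_accession, ap$focal_accession)
  expect_equal(ap2$per_chromosome_closest, ap$per_chromosome_closest)
})
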