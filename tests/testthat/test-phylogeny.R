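test_that("RSCU distances are squared-Euclidean with pairwise deletion", {
  m <- rscu_matrix(generate_cds(synthetic_spec(3, 200, seed = 2)))
  d <- rscu_distance_matrix(m)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d[1, 2], sum((m[, 1] - m[, 2])^2, na.rm = TRUE))

  # identical profiles at distance zero; a single 2-unit gap scores 4
  p <- matrix(1, nrow = 59, ncol = 2,
              dimnames = list(genetic_code()$synonymous, c("a", "b")))
  expect_equal(rscu_distance_matrix(p)["a", "b"], 0)
  p[1, 2] <- 3
  expect_equal(rscu_distance_matrix(p)["a", "b"], 4)

  # undefined codons are skipped, not treated as zero
  q <- p
  q[2:10, 1] <- NA
  expect_equal(rscu_distance_matrix(q)["a", "b"], 4)
  r <- matrix(c(1, rep(NA, 58), rep(1, 59)), ncol = 2,
              dimnames = list(genetic_code()$synonymous, c("a", "b")))
  expect_error(rscu_distance_matrix(r), "fewer than")
})

test_that("hierarchical clustering merges nearest pairs first", {
  d <- matrix(c(0, 1, 10, 1, 0, 11, 10, 11, 0), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cl <- hierarchical_cluster(d)
  expect_equal(cl$hclust$merge[1, ], c(-1, -2))  # A and B merge first
  expect_setequal(cl$leaf_order, c("A", "B", "C"))

  # order invariance with distinct distances
  x <- generate_cds(synthetic_spec(8, 300, codon_preference = 0.4,
                                   gc3_target = 0.5, seed = 6))
  m <- rscu_matrix(x)
  d1 <- rscu_distance_matrix(m)
  perm <- c(5, 1, 8, 3, 7, 2, 6, 4)
  d2 <- rscu_distance_matrix(m[, perm])
  t1 <- hierarchical_cluster(d1)$phylo
  t2 <- hierarchical_cluster(d2)$phylo
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
})

test_that("well-separated AT- and GC-preferring groups split at the root", {
  at <- generate_cds(synthetic_spec(4, 400, codon_preference = 0.5,
                                    gc3_target = 0.15, group = "AT",
                                    seed = 3))
  gc <- generate_cds(synthetic_spec(4, 400, codon_preference = 0.5,
                                    gc3_target = 0.85, group = "GC",
                                    seed = 4))
  both <- cds_set(c(at$id, gc$id), c(at$seq, gc$seq),
                  group = c(at$group, gc$group), validate = FALSE)
  cl <- hierarchical_cluster(rscu_distance_matrix(rscu_matrix(both)))
  # the two top-level clusters are exactly the AT and GC groups
  top <- stats::cutree(cl$hclust, k = 2)
  expect_equal(length(unique(top[at$id])), 1)
  expect_equal(length(unique(top[gc$id])), 1)
  expect_false(top[at$id[1]] == top[gc$id[1]])
})

test_that("p-distances follow mismatches over aligned columns", {
  x <- cds_set(c("s1", "s2", "s3"),
               c("AAATTTGGA", "AAATTTGGA", "AATTTTGGA"))
  d <- pairwise_cds_distance(x)
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], 1 / 9)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))

  y <- cds_set(c("a", "b"), c("AAA", "AAT"))
  expect_equal(pairwise_cds_distance(y)["a", "b"], 1 / 3)
})

test_that("neighbor-joining recovers additive trees exactly", {
  # closed-form three-taxon star
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  expect_s3_class(tr, "phylo")
  lens <- stats::setNames(
    tr$edge.length[match(seq_len(3), tr$edge[, 2])], tr$tip.label)
  expect_equal(lens[["A"]], (3 + 4 - 5) / 2)  # 1
  expect_equal(lens[["B"]], (3 + 5 - 4) / 2)  # 2
  expect_equal(lens[["C"]], (4 + 5 - 3) / 2)  # 3

  set.seed(4)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n)
    d <- stats::cophenetic(true)
    est <- neighbor_joining(d)
    expect_equal(ape::dist.topo(ape::unroot(true), est), 0,
                 ignore_attr = TRUE)
    expect_equal(stats::cophenetic(est)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }

  # ultrametric input: same topology as average-linkage clustering
  coal <- ape::rcoal(6)
  dmat <- stats::cophenetic(coal)
  hc <- hierarchical_cluster(dmat, linkage = "average")$phylo
  nj_tree <- neighbor_joining(dmat)
  expect_equal(ape::dist.topo(ape::unroot(hc), nj_tree), 0,
               ignore_attr = TRUE)

  # negative branch lengths are clamped with a warning
  dbad <- matrix(c(0, 1, 6, 6, 1, 0, 6, 6, 6, 6, 0, 1, 6, 6, 1, 0) * 1.0,
                 nrow = 4, dimnames = list(letters[1:4], letters[1:4]))
  dbad["a", "b"] <- 5.9
  dbad["b", "a"] <- 5.9
  dbad["a", "c"] <- 0.1
  dbad["c", "a"] <- 0.1
  expect_warning(trc <- neighbor_joining(dbad), "clamped")
  expect_true(all(trc$edge.length >= 0))

  expect_error(neighbor_joining(matrix(c(0, Inf, Inf, 0), 2)),
               "non-finite|at least 3")
})

test_that("Newick serialisation round-trips topology and lengths", {
  tr <- ape::rtree(2)
  tr$tip.label <- c("A", "B")
  txt <- write_newick(tr)
  expect_match(txt, "^\\(A:[0-9.]+,B:[0-9.]+\\);$")

  set.seed(8)
  tr <- ape::rtree(32)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- ape::read.tree(path)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-6)

  cl <- hierarchical_cluster(stats::cophenetic(ape::rcoal(5)))
  expect_match(write_newick(cl), ";$")
})
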