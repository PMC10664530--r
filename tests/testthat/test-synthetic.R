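test_that("generation is deterministic and self-consistent", {
  spec <- synthetic_spec(4, c(50, 120), codon_preference = 0.4,
                         gc3_target = 0.6, seed = 17)
  x <- generate_cds(spec)
  y <- generate_cds(spec)
  expect_identical(x$seq, y$seq)

  # realised codon counts match the draw log exactly
  log <- attr(x, "draw_log")
  for (i in seq_len(nrow(x))) {
    cnt <- count_codons(x$seq[i], validated = TRUE)
    expect_equal(unclass(cnt), log[[x$id[i]]], ignore_attr = TRUE)
  }

  # terminal stop was appended then stripped by validation
  expect_true(all(nchar(x$seq) %% 3 == 0))
  expect_false(any(grepl("(TAA|TAG|TGA)$", substring(x$seq,
                                                     nchar(x$seq) - 2))))
  expect_true(all(vapply(attr(x, "warnings"),
                         function(w) any(grepl("terminal stop", w)),
                         logical(1))))
})

test_that("per-family distributions sum to one and respect the dials", {
  spec <- synthetic_spec(1, 100, codon_preference = 0.7, gc3_target = 0.3,
                         seed = 1)
  dists <- codon_distributions(spec)
  expect_equal(unname(vapply(dists, sum, numeric(1))), rep(1, 18))

  # strength 1 concentrates every family on its preferred codon
  spec1 <- synthetic_spec(1, 100, codon_preference = 1, seed = 1)
  d1 <- codon_distributions(spec1)
  pref <- default_preferred_codons()
  for (aa in names(d1)) {
    expect_equal(unname(d1[[aa]][pref[[aa]]]), 1)
  }

  # infeasible GC3 target under a fully concentrated family profile
  expect_error(
    codon_distributions(synthetic_spec(1, 100, codon_preference = 1,
                                       gc3_target = 0.9, seed = 1)),
    "infeasible")
})

test_that("preference strength drives ENC between its bounds", {
  u <- generate_cds(synthetic_spec(1, 10000, codon_preference = 0,
                                   seed = 2))
  e_u <- enc(count_codons(u$seq[1], validated = TRUE))
  expect_lt(abs(as.numeric(e_u) - 61), 1)

  p <- generate_cds(synthetic_spec(1, 1000, codon_preference = 1,
                                   seed = 2))
  expect_equal(as.numeric(enc(count_codons(p$seq[1], validated = TRUE))),
               20)
})

test_that("pooled RSCU converges to the spec-implied profile", {
  x <- generate_cds(synthetic_spec(10, 10000, codon_preference = 0.3,
                                   gc3_target = 0.55, seed = 21))
  pooled <- Reduce(`+`, attr(x, "draw_log"))
  r <- rscu(as_codon_counts(pooled))
  dists <- attr(x, "distributions")
  implied <- unlist(lapply(dists, function(p) p * length(p)))
  names(implied) <- unlist(lapply(dists, names))
  expect_lt(max(abs(r[names(implied)] - implied)), 0.1)
})

test_that("the apicomplexan-style cohort matches its study design", {
  x <- generate_apicomplexan_cohort(seed = 1)
  expect_equal(nrow(x), 32)
  expect_equal(sort(unique(x$group)),
               sort(c("Babesia", "Cryptosporidium", "Eimeria",
                      "Plasmodium", "Theileria", "Other")))
  expect_true(all(nchar(x$seq) >= 255 & nchar(x$seq) <= 1665))

  comp <- composition_table(x)
  at_rich <- comp$GC3[comp$group %in% c("Cryptosporidium", "Plasmodium")]
  gc_rich <- comp$GC3[comp$group %in% c("Babesia", "Eimeria", "Other")]
  expect_lt(mean(at_rich), mean(gc_rich))

  # RSCU clustering separates AT-rich from GC-rich groups at the top split
  sub <- comp$group %in% c("Cryptosporidium", "Plasmodium", "Babesia",
                           "Eimeria", "Other")
  cl <- hierarchical_cluster(rscu_distance_matrix(rscu_matrix(x[sub, ])))
  top <- stats::cutree(cl$hclust, k = 2)
  side <- vapply(split(top, comp$group[sub] %in%
                         c("Cryptosporidium", "Plasmodium")),
                 function(v) mean(v == 1), numeric(1))
  expect_true(all(side %in% c(0, 1)))
  expect_equal(sum(side), 1)
})

test_that("mutation-pressure profiles couple all three codon positions", {
  prof <- mutation_pressure_profile(0.7)
  expect_equal(sum(prof$aa_frequencies), 1)
  expect_equal(unname(vapply(prof$codon_preference, sum, numeric(1))),
               rep(1, 18))
  # GC-rich pressure favours GC-rich amino acids (e.g. Ala GCN over Lys AAR)
  expect_gt(prof$aa_frequencies[["A"]], prof$aa_frequencies[["K"]])
})
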