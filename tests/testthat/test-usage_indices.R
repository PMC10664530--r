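test_that("RSCU follows the uniform-expectation formula", {
  r <- rscu(as_codon_counts(c(AAA = 3, AAG = 1)))
  expect_equal(unname(r[c("AAA", "AAG")]), c(1.5, 0.5))

  # uniform usage within every family gives RSCU 1 everywhere
  code <- genetic_code()
  uniform <- stats::setNames(rep(1L, 59), code$synonymous)
  r <- rscu(as_codon_counts(uniform))
  expect_true(all(abs(r - 1) < 1e-12))

  # one codon carrying a 6-fold family reaches its degeneracy
  r <- rscu(as_codon_counts(c(AGA = 7)))
  expect_equal(unname(r[["AGA"]]), 6)
  # codons of unobserved amino acids are undefined, not zero
  expect_true(is.na(r[["AAA"]]))

  # family sums equal degeneracy for every observed amino acid
  set.seed(3)
  cnt <- count_codons(random_cds(150))
  r <- rscu(cnt)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    if (sum(cnt[fam]) > 0) {
      expect_equal(sum(r[fam]), code$degeneracy[[aa]])
    }
  }
})

test_that("ENC hits its boundaries and is clamped at 61", {
  code <- genetic_code()
  # one codon per family, each seen twice -> ENC = 20 exactly
  one_per <- stats::setNames(
    rep(2L, 18), vapply(code$families, `[`, character(1), 1))
  expect_equal(as.numeric(enc(as_codon_counts(one_per))), 20)

  # exactly uniform finite usage estimates above 61 and is clamped
  uniform <- stats::setNames(rep(10L, 59), code$synonymous)
  e <- enc(as_codon_counts(uniform))
  expect_equal(as.numeric(e), 61)
  expect_gt(attr(e, "raw"), 61)

  expect_error(enc(as_codon_counts(c(AAA = 1))), "undefined")
})

test_that("ENC is order-invariant and converges under count scaling", {
  set.seed(9)
  s <- random_cds(500)
  cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  shuffled <- paste(sample(cods), collapse = "")
  expect_equal(as.numeric(enc(count_codons(s))),
               as.numeric(enc(count_codons(shuffled))))

  cnt <- count_codons(s)
  e1 <- attr(enc(cnt), "raw")
  e50 <- attr(enc(as_codon_counts(unclass(cnt) * 50L)), "raw")
  einf <- attr(enc(as_codon_counts(unclass(cnt) * 5000L)), "raw")
  # scaling shrinks the small-sample correction monotonically
  expect_lt(abs(e50 - einf), abs(e1 - einf))
  expect_lt(abs(e50 - einf), 0.2)
})

test_that("CAI, CBI and FOP behave on hand-computable inputs", {
  code <- genetic_code()
  ref <- default_reference_weights()

  # sequence using only weight-1 codons has CAI 1
  all_opt <- stats::setNames(rep(3L, 18), unname(ref$optimal))
  expect_equal(cai(as_codon_counts(all_opt), ref), 1)
  expect_equal(cbi(as_codon_counts(all_opt), ref), 1)
  expect_equal(fop(as_codon_counts(all_opt), ref), 1)

  # geometric mean of 1 and 0.25 is 0.5
  w <- stats::setNames(rep(1, 59), code$synonymous)
  w["AAG"] <- 0.25
  toy <- reference_weights(w)
  expect_equal(cai(as_codon_counts(c(AAA = 1, AAG = 1)), toy), 0.5)

  # uniform family usage: CBI = 0, FOP = expected-uniform value
  uniform <- stats::setNames(rep(4L, 59), code$synonymous)
  expect_equal(cbi(as_codon_counts(uniform), ref), 0)
  expect_equal(fop(as_codon_counts(uniform), ref), 18 * 4 / (59 * 4))

  # Lys-only with optimal AAG: CBI = (1 - 2)/(4 - 2), FOP = 1/4
  w2 <- stats::setNames(rep(1, 59), code$synonymous)
  w2["AAA"] <- 0.5
  ref_aag <- reference_weights(w2)
  expect_equal(ref_aag$optimal[["K"]], "AAG")
  lys <- as_codon_counts(c(AAA = 3, AAG = 1))
  expect_equal(cbi(lys, ref_aag), -0.5)
  expect_equal(fop(lys, ref_aag), 0.25)
  # no optimal codons present
  expect_equal(fop(as_codon_counts(c(AAA = 4)), ref_aag), 0)
})

test_that("reference weight construction normalises and floors", {
  expect_error(reference_weights(c(AAA = 1)), "missing")
  w <- stats::setNames(rep(2, 59), genetic_code()$synonymous)
  ref <- reference_weights(w)
  expect_true(all(abs(ref$w - 1) < 1e-12))

  # zero-count codons get the 0.5 pseudo-count
  counts <- stats::setNames(rep(10, 59), genetic_code()$synonymous)
  counts["AAG"] <- 0
  ref <- compute_reference_weights(counts)
  expect_equal(unname(ref$w[["AAG"]]), 0.05)
  expect_true(all(ref$w > 0))
})

test_that("reference weights round-trip through the text format", {
  ref <- default_reference_weights()
  path <- withr::local_tempfile(fileext = ".tsv")
  opt_aa <- stats::setNames(names(ref$optimal), unname(ref$optimal))
  writeLines(c("# codon weight optimal_aa",
               sprintf("%s\t%.6f\t%s", names(ref$w), ref$w,
                       ifelse(is.na(opt_aa[names(ref$w)]), "",
                              opt_aa[names(ref$w)]))), path)
  back <- read_reference_weights(path)
  expect_equal(back$w, ref$w, tolerance = 1e-6)
  expect_equal(back$optimal, ref$optimal)
})

test_that("GRAVY and AROMO follow their residue tables", {
  expect_equal(gravy("GG"), -0.4)
  expect_equal(gravy("II"), 4.5)
  expect_equal(gravy("MKFY"), gravy("YFKM"))  # order invariance
  expect_error(gravy("MKX"), "unknown residue")

  expect_equal(aromo("FYWA"), 0.75)
  expect_equal(aromo("AAAA"), 0)
  expect_equal(aromo("FFFF"), 1)
  expect_error(aromo(""), "empty")
})

test_that("every index matches the brute-force oracle on random CDSs", {
  ref <- default_reference_weights()
  set.seed(101)
  for (i in 1:20) {
    s <- random_cds(sample(30:80, 1))
    cnt <- count_codons(s, validated = TRUE)
    prot <- translate_cds(s, validated = TRUE)

    expect_equal(unclass(position_composition(cnt)), oracle_composition(s),
                 tolerance = 1e-9)
    r <- rscu(cnt)
    o <- oracle_rscu(s)
    expect_equal(unclass(r)[names(o)], o, tolerance = 1e-9)
    expect_equal(as.numeric(enc(cnt)), oracle_enc(s), tolerance = 1e-9)
    expect_equal(cai(cnt, ref), oracle_cai(s, ref), tolerance = 1e-9)
    oc <- oracle_cbi_fop(s, ref)
    expect_equal(cbi(cnt, ref), unname(oc["CBI"]), tolerance = 1e-9)
    expect_equal(fop(cnt, ref), unname(oc["FOP"]), tolerance = 1e-9)
    expect_equal(gravy(prot), oracle_gravy(oracle_protein(s)),
                 tolerance = 1e-9)
    expect_equal(aromo(prot), oracle_aromo(oracle_protein(s)),
                 tolerance = 1e-9)
    expect_equal(cds_lengths(cnt), oracle_lengths(s))
  }
})

test_that("index_table composes the per-sequence operations", {
  x <- generate_cds(synthetic_spec(3, 120, codon_preference = 0.3,
                                   seed = 13))
  tab <- index_table(x)
  expect_equal(nrow(tab), 3)
  cnt <- count_codons(x$seq[2], validated = TRUE)
  expect_equal(tab$ENC[2], as.numeric(enc(cnt)))
  expect_equal(tab$CAI[2], cai(cnt))
  expect_equal(unname(tab$L_sym[2]), unname(cds_lengths(cnt)["L_sym"]))

  # deterministic: regenerating the cohort reproduces the table exactly
  y <- generate_cds(synthetic_spec(3, 120, codon_preference = 0.3,
                                   seed = 13))
  expect_identical(index_table(y), tab)

  # a degenerate row is flagged, not fatal
  bad <- cds_set(c("ok", "met"), c("AAAAAATTTTTTGGAGGA", "ATGATGATG"))
  tab2 <- index_table(bad)
  expect_true(is.na(tab2$ENC[2]))
  expect_named(attr(tab2, "problems"), "met")
  expect_false(anyNA(tab2[1, c("CAI", "ENC", "GRAVY")]))
})
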