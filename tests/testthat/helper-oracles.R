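# Independent brute-force oracles. These recompute every statistic
# directly from the raw nucleotide string with plain loops and the
# textbook formulas, sharing no code with the package internals beyond
# the standard genetic code table itself.

oracle_code <- local({
  c2a <- Biostrings::GENETIC_CODE
  syn_aa <- setdiff(unique(unname(c2a)), c("M", "W", "*"))
  list(c2a = c2a, syn_aa = syn_aa,
       syn_codons = names(c2a)[unname(c2a) %in% syn_aa])
})

oracle_triplets <- function(seq) {
  out <- character(0)
  i <- 1
  while (i + 2 <= nchar(seq)) {
    out <- c(out, substr(seq, i, i + 2))
    i <- i + 3
  }
  out
}

# A3/T3/G3/C3, GC1..GC3, GC12, GCs, ATs over synonymous codons, percent.
oracle_composition <- function(seq) {
  cods <- oracle_triplets(seq)
  cods <- cods[oracle_code$c2a[cods] %in% oracle_code$syn_aa]
  n <- length(cods)
  third <- substr(cods, 3, 3)
  gc_frac <- function(pos) {
    100 * sum(substr(cods, pos, pos) %in% c("G", "C")) / n
  }
  gc1 <- gc_frac(1); gc2 <- gc_frac(2); gc3 <- gc_frac(3)
  all_bases <- unlist(strsplit(cods, ""))
  gcs <- 100 * sum(all_bases %in% c("G", "C")) / length(all_bases)
  c(A3 = 100 * sum(third == "A") / n, T3 = 100 * sum(third == "T") / n,
    G3 = 100 * sum(third == "G") / n, C3 = 100 * sum(third == "C") / n,
    GC1 = gc1, GC2 = gc2, GC3 = gc3, GC12 = (gc1 + gc2) / 2,
    GCs = gcs, ATs = 100 - gcs)
}

oracle_rscu <- function(seq) {
  cods <- oracle_triplets(seq)
  out <- c()
  for (aa in oracle_code$syn_aa) {
    fam <- names(oracle_code$c2a)[oracle_code$c2a == aa]
    tot <- sum(cods %in% fam)
    for (codon in fam) {
      out[codon] <- if (tot == 0) NA_real_ else {
        sum(cods == codon) / (tot / length(fam))
      }
    }
  }
  out
}

oracle_enc <- function(seq) {
  cods <- oracle_triplets(seq)
  F_by_deg <- list(`2` = c(), `3` = c(), `4` = c(), `6` = c())
  for (aa in oracle_code$syn_aa) {
    fam <- names(oracle_code$c2a)[oracle_code$c2a == aa]
    n <- sum(cods %in% fam)
    if (n < 2) next
    sum_p2 <- 0
    for (codon in fam) sum_p2 <- sum_p2 + (sum(cods == codon) / n)^2
    Fa <- (n * sum_p2 - 1) / (n - 1)
    k <- as.character(length(fam))
    F_by_deg[[k]] <- c(F_by_deg[[k]], Fa)
  }
  fbar <- sapply(F_by_deg, function(v) if (length(v)) mean(v) else NA_real_)
  fbar[!is.na(fbar) & fbar <= 0] <- NA
  orig <- fbar
  def <- which(!is.na(orig))
  if (is.na(orig["3"]) && !is.na(orig["2"]) && !is.na(orig["4"])) {
    fbar["3"] <- 2 / (1 / orig["2"] + 1 / orig["4"])
  }
  for (k in names(fbar)[is.na(fbar)]) {
    pos <- match(k, names(fbar))
    below <- def[def < pos]; above <- def[def > pos]
    fbar[k] <- mean(c(if (length(below)) orig[max(below)],
                      if (length(above)) orig[min(above)]))
  }
  val <- 2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] + 5 / fbar[["4"]] +
    3 / fbar[["6"]]
  min(val, 61)
}

# Literal geometric mean (product form); safe for the short test sequences.
oracle_cai <- function(seq, ref) {
  cods <- oracle_triplets(seq)
  cods <- cods[cods %in% oracle_code$syn_codons]
  prod(ref$w[cods])^(1 / length(cods))
}

oracle_cbi_fop <- function(seq, ref) {
  cods <- oracle_triplets(seq)
  cods <- cods[cods %in% oracle_code$syn_codons]
  n_tot <- length(cods)
  n_opt <- sum(cods %in% ref$optimal)
  n_ran <- 0
  for (aa in oracle_code$syn_aa) {
    fam <- names(oracle_code$c2a)[oracle_code$c2a == aa]
    n_ran <- n_ran + sum(cods %in% fam) / length(fam)
  }
  c(CBI = (n_opt - n_ran) / (n_tot - n_ran), FOP = n_opt / n_tot)
}

oracle_kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)

oracle_protein <- function(seq) {
  aa <- unname(oracle_code$c2a[oracle_triplets(seq)])
  paste(aa[aa != "*"], collapse = "")
}

oracle_gravy <- function(protein) {
  mean(oracle_kd[strsplit(protein, "")[[1]]])
}

oracle_aromo <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  sum(aa %in% c("F", "Y", "W")) / length(aa)
}

oracle_lengths <- function(seq) {
  cods <- oracle_triplets(seq)
  aa <- unname(oracle_code$c2a[cods])
  c(L_sym = sum(aa %in% oracle_code$syn_aa), L_aa = sum(aa != "*"))
}

# A random in-frame stop-free CDS (uniform over the 61 sense codons).
random_cds <- function(n_codons) {
  sense <- names(oracle_code$c2a)[oracle_code$c2a != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
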