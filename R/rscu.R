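#' Relative synonymous codon usage
#'
#' RSCU of a codon is its observed count divided by the count expected if
#' all codons of its family were used uniformly:
#' `RSCU_c = n_c / (family_total / degeneracy)`. A value of 1 means
#' unbiased usage; values above 1 (above 1.6, strongly) mark preferred
#' codons; a single codon carrying a whole 6-fold family reaches 6. Codons
#' of amino acids that never occur in the sequence are reported as `NA`
#' (undefined), not 0, so that downstream distances can use
#' pairwise-complete handling instead of fabricating dissimilarity.
#'
#' @param x A nucleotide string or a `codon_counts` object.
#' @return A named numeric vector of class `rscu` over the 59 synonymous
#'   codons, with attribute `"aa"` giving each codon's amino acid.
#' @examples
#' rscu(as_codon_counts(c(AAA = 3, AAG = 1)))[c("AAA", "AAG")]  # 1.5, 0.5
#' @export
rscu <- function(x) {
  counts <- as_codon_counts(x)
  code <- genetic_code()
  syn <- code$synonymous
  if (sum(counts[syn]) == 0L) {
    stop("no synonymous codons observed; RSCU is undefined")
  }
  out <- stats::setNames(rep(NA_real_, length(syn)), syn)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    tot <- sum(counts[fam])
    if (tot > 0L) {
      out[fam] <- counts[fam] / (tot / length(fam))
    }
  }
  structure(out, aa = unname(code$codon_to_aa[syn]), class = "rscu")
}

#' @export
print.rscu <- function(x, digits = 3, ...) {
  df <- data.frame(codon = names(x), aa = attr(x, "aa"),
                   RSCU = round(unclass(x), digits))
  rownames(df) <- NULL
  print(df[order(df$aa, df$codon), ], row.names = FALSE)
  invisible(x)
}

#' RSCU matrix for a sequence cohort
#'
#' @param x A [cds_set()].
#' @return A 59 x n numeric matrix (codons x sequences, columns named by
#'   id) with `NA` for codons of unobserved amino acids.
#' @export
rscu_matrix <- function(x) {
  stopifnot(inherits(x, "cds_set"))
  cols <- lapply(x$seq, function(s) {
    unclass(rscu(count_codons(s, validated = TRUE)))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- x$id
  m
}
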