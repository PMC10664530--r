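#' Per-position nucleotide composition over the synonymous codon set
#'
#' Computes the third-position base contents (A3, T3, G3, C3), the G+C
#' content at each codon position (GC1, GC2, GC3), their average over the
#' first two positions (GC12), and the overall G+C / A+T contents (GCs,
#' ATs), all in percent and all restricted to the 59-codon synonymous set
#' (stops, ATG and TGG never contribute). Because each position contributes
#' exactly one base per retained codon, GCs equals the mean of GC1, GC2 and
#' GC3.
#'
#' @param x A nucleotide string or a `codon_counts` object.
#' @return A named numeric vector of class `position_composition` with
#'   elements A3, T3, G3, C3, GC1, GC2, GC3, GC12, GCs, ATs (percent).
#' @examples
#' position_composition(count_codons("AAAGGGAAAGGG"))
#' @export
position_composition <- function(x) {
  counts <- as_codon_counts(x)
  code <- genetic_code()
  syn <- code$synonymous
  n_syn <- counts[syn]
  total <- sum(n_syn)
  if (total == 0L) {
    stop("no synonymous codons observed; composition is undefined")
  }
  base_at <- function(pos, base) {
    100 * sum(n_syn[substr(syn, pos, pos) == base]) / total
  }
  gc_at <- function(pos) {
    100 * sum(n_syn[substr(syn, pos, pos) %in% c("G", "C")]) / total
  }
  gc1 <- gc_at(1L); gc2 <- gc_at(2L); gc3 <- gc_at(3L)
  gcs <- 100 * sum(n_syn * vapply(
    syn, function(cod) sum(strsplit(cod, "")[[1]] %in% c("G", "C")),
    numeric(1))) / (3 * total)
  out <- c(
    A3 = base_at(3L, "A"), T3 = base_at(3L, "T"),
    G3 = base_at(3L, "G"), C3 = base_at(3L, "C"),
    GC1 = gc1, GC2 = gc2, GC3 = gc3,
    GC12 = (gc1 + gc2) / 2,
    GCs = gcs, ATs = 100 - gcs
  )
  class(out) <- "position_composition"
  out
}

#' @export
print.position_composition <- function(x, digits = 2, ...) {
  print(round(unclass(x), digits))
  invisible(x)
}

#' Composition table for a sequence cohort
#'
#' One row per sequence with the ten [position_composition()] statistics,
#' mirroring the column layout of classic codon-usage composition tables
#' (species, A3, T3, G3, C3, GC1, GC2, GC3, GC12, GCs, ATs).
#'
#' @param x A [cds_set()].
#' @return A data frame keyed by `id` with `species` and `group` carried
#'   through; values in percent at full precision.
#' @export
composition_table <- function(x) {
  stopifnot(inherits(x, "cds_set"))
  rows <- lapply(x$seq, function(s) {
    unclass(position_composition(count_codons(s, validated = TRUE)))
  })
  out <- cbind(
    x[, c("id", "species", "group")],
    as.data.frame(do.call(rbind, rows))
  )
  rownames(out) <- NULL
  out
}
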