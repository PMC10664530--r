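#' The standard genetic code, organised for codon-usage statistics
#'
#' Returns the standard nuclear genetic code together with the bookkeeping
#' needed by codon-usage-bias statistics: the synonymous families, their
#' degeneracies, and the 59-codon synonymous set obtained by removing the
#' three stop codons and the single-codon families ATG (Met) and TGG (Trp).
#' All bias statistics in this package (composition, RSCU, ENC, CAI, CBI,
#' FOP) are restricted to these 59 codons, which encode 18 amino acids.
#'
#' @return An object of class `genetic_code`: a list with elements
#'   `codon_to_aa` (named character vector over all 64 codons, stops as
#'   `"*"`), `families` (list mapping each of the 18 multi-codon amino acids
#'   to its synonymous codons), `degeneracy` (named integer vector of family
#'   sizes, values in \{2, 3, 4, 6\}), `synonymous` (the 59 retained codons)
#'   and `stop_codons`.
#' @examples
#' code <- genetic_code()
#' length(code$synonymous)   # 59
#' sum(code$degeneracy)      # 59
#' @export
genetic_code <- function() {
  if (!is.null(.cubkit_env$code)) {
    return(.cubkit_env$code)
  }
  c2a <- Biostrings::GENETIC_CODE
  codons <- names(c2a)
  aa <- unname(c2a)
  multi_aa <- setdiff(sort(unique(aa)), c("M", "W", "*"))
  families <- lapply(multi_aa, function(a) sort(codons[aa == a]))
  names(families) <- multi_aa
  degeneracy <- vapply(families, length, integer(1))
  code <- structure(
    list(
      codon_to_aa = c2a,
      families    = families,
      degeneracy  = degeneracy,
      synonymous  = sort(unlist(families, use.names = FALSE)),
      stop_codons = sort(codons[aa == "*"])
    ),
    class = "genetic_code"
  )
  .cubkit_env$code <- code
  code
}

.cubkit_env <- new.env(parent = emptyenv())

#' @export
print.genetic_code <- function(x, ...) {
  cat("Standard genetic code:", length(x$codon_to_aa), "codons;",
      length(x$families), "synonymous families covering",
      length(x$synonymous), "codons\n")
  invisible(x)
}

## Split a nucleotide string into its consecutive triplets.
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return(character(0))
  starts <- seq.int(1L, n - n %% 3L, by = 3L)
  substring(seq, starts, starts + 2L)
}

#' Validate and clean a coding sequence
#'
#' Normalises a CDS for downstream codon statistics: uppercases, converts
#' U to T, enforces the reading frame, drops codons containing ambiguous
#' (non-ACGT) bases, strips a terminal stop codon, and warns about internal
#' stop codons (a pseudogene guard; internal stops do not abort).
#'
#' @param x Character vector of nucleotide sequences.
#' @param policy `"lenient"` (default) trims a trailing partial codon with a
#'   warning; `"strict"` raises an error when the length is not a multiple
#'   of three.
#' @return A character vector of cleaned sequences (each a multiple of three
#'   long, over A/C/G/T only) with an attribute `"warnings"`: a list, one
#'   character vector of messages per input sequence.
#' @examples
#' validate_cds("ATGAAATAA")       # terminal stop removed -> "ATGAAA"
#' validate_cds("ATGAANAAA")       # ambiguous codon AAN dropped
#' @export
validate_cds <- function(x, policy = c("lenient", "strict")) {
  policy <- match.arg(policy)
  code <- genetic_code()
  out <- character(length(x))
  warns <- vector("list", length(x))
  for (i in seq_along(x)) {
    s <- chartr("u", "T", chartr("U", "T", toupper(x[[i]])))
    s <- gsub("[ \t\r\n]", "", s)
    w <- character(0)
    if (nchar(s) %% 3L != 0L) {
      if (policy == "strict") {
        stop("sequence ", i, ": length ", nchar(s),
             " is not a multiple of 3 (frame error)")
      }
      w <- c(w, sprintf("trailing partial codon of %d nt dropped",
                        nchar(s) %% 3L))
      s <- substr(s, 1L, nchar(s) - nchar(s) %% 3L)
    }
    cod <- split_codons(s)
    bad <- grepl("[^ACGT]", cod)
    if (any(bad)) {
      w <- c(w, sprintf("%d codon(s) with ambiguous bases dropped", sum(bad)))
      cod <- cod[!bad]
    }
    is_stop <- cod %in% code$stop_codons
    if (length(cod) && is_stop[length(cod)]) {
      w <- c(w, "terminal stop removed")
      cod <- cod[-length(cod)]
      is_stop <- is_stop[-length(is_stop)]
    }
    if (any(is_stop)) {
      w <- c(w, sprintf("%d internal stop codon(s) present", sum(is_stop)))
    }
    if (!length(cod)) {
      stop("sequence ", i, ": empty after cleaning (degenerate input)")
    }
    out[i] <- paste(cod, collapse = "")
    warns[[i]] <- w
  }
  names(out) <- names(x)
  attr(out, "warnings") <- warns
  out
}

#' Count codon occurrences in a coding sequence
#'
#' @param x A single nucleotide string (validated with [validate_cds()]
#'   unless `validated = TRUE` says it already was).
#' @param validated Set `TRUE` to skip re-validation.
#' @return A named integer vector of class `codon_counts` over all 64
#'   codons, with attribute `total` (the number of codons counted, i.e.
#'   `nchar(x) / 3`).
#' @examples
#' count_codons("AAAAAAAAG")[c("AAA", "AAG")]
#' @export
count_codons <- function(x, validated = FALSE) {
  stopifnot(length(x) == 1L)
  if (!validated) x <- validate_cds(x)
  code <- genetic_code()
  tab <- table(factor(split_codons(x), levels = names(code$codon_to_aa)))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  structure(counts, class = "codon_counts", total = sum(counts))
}

#' Coerce to a codon-count table
#'
#' Accepts an existing `codon_counts` object, a nucleotide string, or a
#' named numeric vector of counts for a subset of codons (missing codons
#' become zero).
#'
#' @param x Object to coerce.
#' @return A `codon_counts` object over all 64 codons.
#' @examples
#' as_codon_counts(c(AAA = 3, AAG = 1))
#' @export
as_codon_counts <- function(x) {
  if (inherits(x, "codon_counts")) return(x)
  if (is.character(x)) return(count_codons(x))
  if (is.numeric(x) && !is.null(names(x))) {
    code <- genetic_code()
    counts <- integer(64L)
    names(counts) <- names(code$codon_to_aa)
    counts[names(x)] <- as.integer(x)
    return(structure(counts, class = "codon_counts", total = sum(counts)))
  }
  stop("cannot interpret input as codon counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("Codon counts over", attr(x, "total"), "codons;",
      sum(x > 0), "distinct codons observed\n")
  print(unclass(x)[x > 0])
  invisible(x)
}

#' Translate a coding sequence with the standard code
#'
#' Stop codons are not represented in the output (a terminal stop is already
#' removed by validation; internal stops, which validation warns about, are
#' skipped).
#'
#' @inheritParams count_codons
#' @return A single amino-acid string in one-letter code.
#' @examples
#' translate_cds("ATGAAA")     # "MK"
#' translate_cds("TTTTATTGG")  # "FYW"
#' @export
translate_cds <- function(x, validated = FALSE) {
  stopifnot(length(x) == 1L)
  if (!validated) x <- validate_cds(x)
  code <- genetic_code()
  aa <- unname(code$codon_to_aa[split_codons(x)])
  paste(aa[aa != "*"], collapse = "")
}

#' Synonymous and translatable codon counts of a sequence
#'
#' `L_aa` is the number of translatable codons (every amino-acid codon,
#' Met and Trp included; stops excluded); `L_sym` counts only codons in the
#' 59-codon synonymous set, the denominator of all bias statistics.
#'
#' @param x A nucleotide string or a `codon_counts` object.
#' @return Named integer vector `c(L_sym, L_aa)`.
#' @examples
#' cds_lengths("ATGAAATAA")  # L_sym = 1, L_aa = 2
#' @export
cds_lengths <- function(x) {
  counts <- as_codon_counts(x)
  code <- genetic_code()
  stops <- code$stop_codons
  c(L_sym = sum(counts[code$synonymous]),
    L_aa  = sum(counts[setdiff(names(counts), stops)]))
}
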