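#' Construct a relative-adaptiveness weight table for CAI / CBI / FOP
#'
#' Weights are normalised within each synonymous family so that the best
#' codon has w = 1; the optimal codon of a family is the one attaining that
#' maximum (lowest codon alphabetically on ties). All 59 synonymous codons
#' must receive a strictly positive weight.
#'
#' @param w Named numeric vector of positive weights covering the 59
#'   synonymous codons (extra codons are ignored).
#' @param optimal Optional named character vector, amino acid -> optimal
#'   codon; derived from `w` when omitted.
#' @param label Free-text provenance label.
#' @return An object of class `reference_weights`: list with `w` (named
#'   over the 59 codons, family maxima equal to 1), `optimal`, `label`.
#' @export
reference_weights <- function(w, optimal = NULL, label = "user") {
  code <- genetic_code()
  syn <- code$synonymous
  missing <- setdiff(syn, names(w))
  if (length(missing)) {
    stop("reference weights missing for codons: ",
         paste(missing, collapse = ", "))
  }
  w <- w[syn]
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("reference weights must be finite and > 0 for all 59 codons")
  }
  opt <- character(0)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    w[fam] <- w[fam] / max(w[fam])
    opt[aa] <- fam[which.max(w[fam])]
  }
  if (!is.null(optimal)) {
    stopifnot(all(names(code$families) %in% names(optimal)))
    optimal <- optimal[names(code$families)]
    bad <- vapply(names(code$families), function(aa) {
      !(optimal[[aa]] %in% code$families[[aa]])
    }, logical(1))
    if (any(bad)) stop("optimal codons outside their family: ",
                       paste(optimal[bad], collapse = ", "))
    opt <- optimal
  }
  structure(list(w = w, optimal = opt, label = label),
            class = "reference_weights")
}

#' @export
print.reference_weights <- function(x, ...) {
  cat("Reference weights (", x$label, "): 59 codons, ",
      length(x$optimal), " optimal codons\n", sep = "")
  invisible(x)
}

#' Derive reference weights from a highly-expressed-gene codon count table
#'
#' Codons unobserved in the reference set receive a 0.5 pseudo-count before
#' within-family normalisation, so every weight is strictly positive.
#'
#' @param counts Named numeric vector of codon counts from a reference gene
#'   set (highly expressed genes).
#' @param label Provenance label.
#' @return A [reference_weights()] object.
#' @export
compute_reference_weights <- function(counts, label = "computed") {
  code <- genetic_code()
  n <- stats::setNames(numeric(length(code$synonymous)), code$synonymous)
  keep <- intersect(names(counts), code$synonymous)
  n[keep] <- counts[keep]
  n[n == 0] <- 0.5
  reference_weights(n, label = label)
}

#' Read a reference-weight table from a text file
#'
#' Whitespace-delimited columns: codon, weight, and optionally the amino
#' acid for which the codon is optimal. Lines starting with `#` are
#' comments.
#'
#' @param path File path.
#' @param label Provenance label; defaults to the file name.
#' @return A [reference_weights()] object.
#' @export
read_reference_weights <- function(path, label = basename(path)) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           fill = TRUE, stringsAsFactors = FALSE)
  w <- stats::setNames(as.numeric(tab[[2]]), toupper(tab[[1]]))
  optimal <- NULL
  if (ncol(tab) >= 3) {
    flagged <- !is.na(tab[[3]]) & tab[[3]] != ""
    if (any(flagged)) {
      optimal <- stats::setNames(toupper(tab[[1]])[flagged],
                                 toupper(tab[[3]])[flagged])
    }
  }
  reference_weights(w, optimal = optimal, label = label)
}

#' Built-in reference: E. coli highly expressed genes
#'
#' The classic relative-adaptiveness table derived from highly expressed
#' *Escherichia coli* genes (the Sharp-Li reference used by most
#' codon-usage software as its default). Use a matched, organism-specific
#' table via [reference_weights()] or [read_reference_weights()] when
#' comparing CAI / CBI / FOP values across tools: these three indices are
#' meaningful only relative to their reference set.
#'
#' @return A [reference_weights()] object.
#' @export
default_reference_weights <- function() {
  w <- c(
    TTT = 0.296, TTC = 1.000, TTA = 0.020, TTG = 0.020,
    CTT = 0.042, CTC = 0.037, CTA = 0.007, CTG = 1.000,
    ATT = 0.185, ATC = 1.000, ATA = 0.003,
    GTT = 1.000, GTC = 0.066, GTA = 0.495, GTG = 0.221,
    TAT = 0.239, TAC = 1.000,
    CAT = 0.291, CAC = 1.000,
    CAA = 0.124, CAG = 1.000,
    AAT = 0.051, AAC = 1.000,
    AAA = 1.000, AAG = 0.253,
    GAT = 0.434, GAC = 1.000,
    GAA = 1.000, GAG = 0.259,
    TCT = 1.000, TCC = 0.744, TCA = 0.077, TCG = 0.017,
    AGT = 0.085, AGC = 0.410,
    CCT = 0.070, CCC = 0.012, CCA = 0.135, CCG = 1.000,
    ACT = 0.965, ACC = 1.000, ACA = 0.076, ACG = 0.099,
    GCT = 1.000, GCC = 0.122, GCA = 0.586, GCG = 0.424,
    TGT = 0.500, TGC = 1.000,
    CGT = 1.000, CGC = 0.356, CGA = 0.004, CGG = 0.004,
    AGA = 0.004, AGG = 0.002,
    GGT = 1.000, GGC = 0.724, GGA = 0.010, GGG = 0.019
  )
  reference_weights(w, label = "E. coli highly expressed genes")
}
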