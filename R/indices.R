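#' Effective number of codons (Wright's Nc)
#'
#' For each amino acid whose family is used `n >= 2` times, the codon
#' homozygosity is `F = (n * sum(p_i^2) - 1) / (n - 1)` with `p_i` the
#' within-family codon frequencies. F is averaged within each degeneracy
#' class (2-, 3-, 4- and 6-fold), and
#' `ENC = 2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6`
#' (the leading 2 accounts for Met and Trp). ENC runs from 20 (one codon
#' per amino acid) to 61 (uniform usage of all 59 codons); estimates above
#' 61, which arise from the small-sample correction, are clamped to 61.
#' When a degeneracy class contributes no amino acid with `n >= 2`, its
#' mean F is imputed: for the 3-fold class (Ile only) `1 / F3` is taken as
#' the average of `1 / F2` and `1 / F4`; any other missing class takes the
#' mean F of the nearest defined classes.
#'
#' @param x A nucleotide string or a `codon_counts` object.
#' @return ENC as a single number in `[20, 61]`, with attribute `"raw"`
#'   holding the unclamped estimate and `"Fbar"` the per-class mean
#'   homozygosities.
#' @export
enc <- function(x) {
  counts <- as_codon_counts(x)
  code <- genetic_code()
  deg <- code$degeneracy
  F_aa <- rep(NA_real_, length(code$families))
  names(F_aa) <- names(code$families)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    n <- sum(counts[fam])
    if (n >= 2L) {
      p <- counts[fam] / n
      F_aa[aa] <- (n * sum(p^2) - 1) / (n - 1)
    }
  }
  classes <- c(2L, 3L, 4L, 6L)
  fbar <- vapply(classes, function(k) {
    vals <- F_aa[deg == k & !is.na(F_aa)]
    if (!length(vals)) return(NA_real_)
    m <- mean(vals)
    if (m <= 0) NA_real_ else m
  }, numeric(1))
  names(fbar) <- classes
  if (all(is.na(fbar))) {
    stop("ENC undefined: no degeneracy class has usable codon usage")
  }
  ## impute missing classes from the originally defined ones
  orig <- fbar
  defined <- which(!is.na(orig))
  if (is.na(orig["3"]) && !is.na(orig["2"]) && !is.na(orig["4"])) {
    fbar["3"] <- 1 / mean(c(1 / orig["2"], 1 / orig["4"]))
  }
  for (i in which(is.na(fbar))) {
    lower <- defined[defined < i]
    upper <- defined[defined > i]
    fbar[i] <- mean(c(if (length(lower)) orig[max(lower)],
                      if (length(upper)) orig[min(upper)]))
  }
  raw <- 2 + 9 / fbar["2"] + 1 / fbar["3"] + 5 / fbar["4"] + 3 / fbar["6"]
  structure(min(unname(raw), 61), raw = unname(raw), Fbar = fbar)
}

#' Codon adaptation index
#'
#' The count-weighted geometric mean of relative-adaptiveness weights over
#' the synonymous codons of the sequence:
#' `CAI = exp( sum(n_c * log(w_c)) / sum(n_c) )`, in `(0, 1]`.
#'
#' @param x A nucleotide string or a `codon_counts` object.
#' @param ref A [reference_weights()] object.
#' @return CAI as a single number.
#' @export
cai <- function(x, ref = default_reference_weights()) {
  counts <- as_codon_counts(x)
  stopifnot(inherits(ref, "reference_weights"))
  syn <- genetic_code()$synonymous
  n <- counts[syn]
  if (sum(n) == 0L) stop("no synonymous codons observed; CAI is undefined")
  w <- ref$w[syn]
  if (any(w <= 0)) stop("invalid reference: non-positive weights")
  exp(sum(n * log(w)) / sum(n))
}

## Optimal-codon bookkeeping shared by CBI and FOP.
.optimal_counts <- function(counts, ref) {
  code <- genetic_code()
  n_tot <- sum(counts[code$synonymous])
  n_opt <- sum(counts[ref$optimal])
  n_ran <- 0
  for (aa in names(code$families)) {
    fam_total <- sum(counts[code$families[[aa]]])
    n_ran <- n_ran + fam_total / code$degeneracy[[aa]]
  }
  list(n_tot = n_tot, n_opt = n_opt, n_ran = n_ran)
}

#' Codon bias index
#'
#' Excess of optimal codons over the expectation under uniform family
#' usage: `CBI = (N_opt - N_ran) / (N_tot - N_ran)` with
#' `N_ran = sum(family_total / degeneracy)`. CBI is 1 when every codon is
#' optimal, 0 under exactly uniform usage, and negative when optimal
#' codons are avoided.
#'
#' @inheritParams cai
#' @return CBI in `[-1, 1]`, or `NA` with a warning in the degenerate case
#'   `N_tot == N_ran`.
#' @export
cbi <- function(x, ref = default_reference_weights()) {
  counts <- as_codon_counts(x)
  stopifnot(inherits(ref, "reference_weights"))
  oc <- .optimal_counts(counts, ref)
  if (oc$n_tot == 0L) stop("no synonymous codons observed; CBI is undefined")
  denom <- oc$n_tot - oc$n_ran
  if (abs(denom) < sqrt(.Machine$double.eps)) {
    warning("CBI undefined: observed total equals the random expectation")
    return(NA_real_)
  }
  (oc$n_opt - oc$n_ran) / denom
}

#' Frequency of optimal codons
#'
#' The fraction of synonymous codons that are the optimal codon of their
#' family: `FOP = N_opt / N_tot`, in `[0, 1]`.
#'
#' @inheritParams cai
#' @return FOP as a single number.
#' @export
fop <- function(x, ref = default_reference_weights()) {
  counts <- as_codon_counts(x)
  stopifnot(inherits(ref, "reference_weights"))
  oc <- .optimal_counts(counts, ref)
  if (oc$n_tot == 0L) stop("no synonymous codons observed; FOP is undefined")
  oc$n_opt / oc$n_tot
}

## Kyte-Doolittle hydropathy indices.
.kyte_doolittle <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of the Kyte-Doolittle hydropathy indices of the
#' residues; positive values indicate hydrophobic proteins, negative
#' hydrophilic.
#'
#' @param protein A single amino-acid string (one-letter code).
#' @return GRAVY as a single number in `[-4.5, 4.5]` (in practice
#'   `[-2, 2]`).
#' @examples
#' gravy("GG")  # -0.4
#' gravy("II")  #  4.5
#' @export
gravy <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1]]
  if (!length(aa)) stop("empty protein")
  unknown <- setdiff(aa, names(.kyte_doolittle))
  if (length(unknown)) {
    stop("unknown residue(s): ", paste(unknown, collapse = ", "))
  }
  mean(.kyte_doolittle[aa])
}

#' Aromaticity (AROMO)
#'
#' Fraction of aromatic residues (Phe, Tyr, Trp) in the protein.
#'
#' @inheritParams gravy
#' @return AROMO in `[0, 1]`.
#' @examples
#' aromo("FYWA")  # 0.75
#' @export
aromo <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1]]
  if (!length(aa)) stop("empty protein")
  unknown <- setdiff(aa, names(.kyte_doolittle))
  if (length(unknown)) {
    stop("unknown residue(s): ", paste(unknown, collapse = ", "))
  }
  mean(aa %in% c("F", "Y", "W"))
}

#' Per-sequence codon-usage index table
#'
#' One row per sequence with CAI, CBI, FOP, ENC, GRAVY, AROMO, L_sym and
#' L_aa, the standard per-gene summary of codon-usage software. Failures
#' on individual sequences are recorded (row left `NA`) without aborting
#' the cohort.
#'
#' @param x A [cds_set()].
#' @param ref A [reference_weights()] object.
#' @return A data frame of class `index_table` keyed by `id`, with
#'   attribute `"problems"` (named character vector of per-row error
#'   messages, if any). Values are kept at full precision; the print
#'   method rounds to 3 decimals.
#' @export
index_table <- function(x, ref = default_reference_weights()) {
  stopifnot(inherits(x, "cds_set"))
  problems <- character(0)
  rows <- lapply(seq_len(nrow(x)), function(i) {
    tryCatch({
      counts <- count_codons(x$seq[i], validated = TRUE)
      prot <- translate_cds(x$seq[i], validated = TRUE)
      len <- cds_lengths(counts)
      c(CAI = cai(counts, ref), CBI = cbi(counts, ref),
        FOP = fop(counts, ref), ENC = as.numeric(enc(counts)),
        GRAVY = gravy(prot), AROMO = aromo(prot),
        L_sym = unname(len["L_sym"]), L_aa = unname(len["L_aa"]))
    }, error = function(e) {
      problems[[x$id[i]]] <<- conditionMessage(e)
      c(CAI = NA_real_, CBI = NA_real_, FOP = NA_real_, ENC = NA_real_,
        GRAVY = NA_real_, AROMO = NA_real_, L_sym = NA_real_,
        L_aa = NA_real_)
    })
  })
  out <- cbind(x[, c("id", "species", "group")],
               as.data.frame(do.call(rbind, rows)))
  rownames(out) <- NULL
  class(out) <- c("index_table", "data.frame")
  attr(out, "problems") <- problems
  out
}

#' @export
print.index_table <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  pr <- attr(x, "problems")
  if (length(pr)) {
    cat("problem rows:", paste(names(pr), collapse = ", "), "\n")
  }
  invisible(x)
}
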