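#' Construct a set of coding sequences
#'
#' A `cds_set` is a plain data frame with one row per CDS and columns `id`,
#' `species`, `group` and `seq`. Group labels follow the six-way design used
#' for grouped regressions: Babesia, Cryptosporidium, Eimeria, Plasmodium,
#' Theileria, Other (free text is accepted).
#'
#' @param id Character vector of unique identifiers.
#' @param seq Character vector of nucleotide sequences (same length as `id`).
#' @param species Species-like labels; defaults to `id`.
#' @param group Group labels; defaults to `NA`.
#' @param validate Clean sequences with [validate_cds()] (default `TRUE`).
#' @return A data frame of class `cds_set`. Validation warnings, if any, are
#'   kept in the `"warnings"` attribute (a list keyed like the rows).
#' @export
cds_set <- function(id, seq, species = id, group = NA_character_,
                    validate = TRUE) {
  stopifnot(length(id) == length(seq), !anyDuplicated(id))
  warns <- NULL
  if (validate) {
    seq <- validate_cds(seq)
    warns <- attr(seq, "warnings")
    names(warns) <- id
    attributes(seq) <- NULL
  }
  out <- data.frame(
    id = as.character(id),
    species = rep_len(as.character(species), length(id)),
    group = rep_len(as.character(group), length(id)),
    seq = as.character(seq),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cds_set", "data.frame")
  attr(out, "warnings") <- warns
  out
}

#' @export
print.cds_set <- function(x, ...) {
  n <- nchar(x$seq)
  cat("cds_set:", nrow(x), "coding sequences,",
      min(n), "-", max(n), "nt\n")
  grp <- table(x$group, useNA = "ifany")
  if (length(grp) > 1L) {
    cat("groups:", paste(sprintf("%s (%d)", names(grp), grp), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Read coding sequences from a FASTA file
#'
#' The first whitespace-delimited token of each header becomes the sequence
#' id; U is normalised to T. An optional sample sheet (columns `id`,
#' `species`, `group`) attaches labels by id.
#'
#' @param path Path to a (multi-)FASTA file.
#' @param samples Optional data frame with columns `id`, `species`, `group`.
#' @param validate Passed to [cds_set()].
#' @return A [cds_set()].
#' @export
read_cds_fasta <- function(path, samples = NULL, validate = TRUE) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("FASTA file contains no sequences: ", path)
  ids <- sub("\\s.*$", "", names(recs))
  seqs <- as.character(recs)
  species <- ids
  group <- NA_character_
  if (!is.null(samples)) {
    stopifnot(all(c("id", "species", "group") %in% names(samples)))
    m <- match(ids, samples$id)
    if (anyNA(m)) {
      stop("sample sheet is missing ids: ",
           paste(ids[is.na(m)], collapse = ", "))
    }
    species <- samples$species[m]
    group <- samples$group[m]
  }
  cds_set(ids, seqs, species = species, group = group, validate = validate)
}

#' Write a `cds_set` to FASTA
#'
#' @param x A [cds_set()].
#' @param path Output file path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "cds_set"))
  set <- Biostrings::DNAStringSet(stats::setNames(x$seq, x$id))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}
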