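#' Squared-Euclidean distances between RSCU profiles
#'
#' `d(i, j)` is the sum of squared RSCU differences over the codons defined
#' in both profiles (pairwise-complete: codons whose amino acid is absent
#' from either sequence are skipped rather than treated as zero, which
#' would fabricate dissimilarity). Distances are independent of sequence
#' length at fixed codon frequencies because RSCU itself is.
#'
#' @param profiles A 59 x n RSCU matrix from [rscu_matrix()], or a
#'   [cds_set()] (converted internally).
#' @param min_shared Minimum number of codons defined in both profiles
#'   (default 2); fewer raises an error.
#' @return A symmetric n x n matrix with zero diagonal, labelled by
#'   sequence id.
#' @export
rscu_distance_matrix <- function(profiles, min_shared = 2L) {
  if (inherits(profiles, "cds_set")) profiles <- rscu_matrix(profiles)
  stopifnot(is.matrix(profiles), ncol(profiles) >= 2L)
  n <- ncol(profiles)
  d <- matrix(0, n, n, dimnames = list(colnames(profiles),
                                       colnames(profiles)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- !is.na(profiles[, i]) & !is.na(profiles[, j])
      if (sum(ok) < min_shared) {
        stop("profiles ", colnames(profiles)[i], " and ",
             colnames(profiles)[j], " share fewer than ", min_shared,
             " defined codons")
      }
      d[i, j] <- d[j, i] <- sum((profiles[ok, i] - profiles[ok, j])^2)
    }
  }
  d
}

#' Hierarchical clustering of a distance matrix
#'
#' Deterministic agglomerative clustering (ties broken by lowest index, as
#' in [stats::hclust()]). The default average linkage is used for RSCU
#' squared-Euclidean distances; `"ward"` maps to `ward.D`, appropriate
#' when the input distances are already squared.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @param linkage One of `"average"`, `"complete"`, `"ward"`.
#' @return A list of class `cub_dendrogram`: `hclust` (the fit), `phylo`
#'   (rooted `ape::phylo` version) and `leaf_order` (labels in plotting
#'   order, for heatmap reuse).
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "complete",
                                                "ward")) {
  linkage <- match.arg(linkage)
  method <- c(average = "average", complete = "complete",
              ward = "ward.D")[[linkage]]
  hc <- stats::hclust(stats::as.dist(d), method = method)
  structure(list(hclust = hc, phylo = ape::as.phylo(hc),
                 leaf_order = hc$labels[hc$order]),
            class = "cub_dendrogram")
}

#' @export
print.cub_dendrogram <- function(x, ...) {
  cat("Hierarchical clustering (", x$hclust$method, " linkage) of ",
      length(x$leaf_order), " profiles\n", sep = "")
  invisible(x)
}

#' Pairwise p-distances between coding sequences
#'
#' Each pair is globally aligned (Needleman-Wunsch; default scores match
#' +1, mismatch -1, gap open -5, gap extend -1) and the p-distance is the
#' number of mismatches divided by the number of aligned columns in which
#' both sequences have a base.
#'
#' @param x A [cds_set()].
#' @param match,mismatch,gap_open,gap_ext Alignment scores (penalties as
#'   positive magnitudes for the gap parameters).
#' @return A symmetric matrix of p-distances in `[0, 1]`, labelled by id.
#' @export
pairwise_cds_distance <- function(x, match = 1, mismatch = -1,
                                  gap_open = 5, gap_ext = 1) {
  stopifnot(inherits(x, "cds_set"), nrow(x) >= 2L)
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE
  )
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(x$id, x$id))
  seqs <- Biostrings::DNAStringSet(stats::setNames(x$seq, x$id))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      aln <- Biostrings::pairwiseAlignment(
        seqs[[i]], seqs[[j]], type = "global",
        substitutionMatrix = sub_mat,
        gapOpening = gap_open, gapExtension = gap_ext
      )
      a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
      b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
      both <- a != "-" & b != "-"
      if (!any(both)) {
        stop("sequences ", x$id[i], " and ", x$id[j],
             " share no aligned bases")
      }
      d[i, j] <- d[j, i] <- sum(a[both] != b[both]) / sum(both)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion and two-point
#' branch-length formulas. On additive distances the generating tree is
#' recovered exactly. Negative branch lengths (a known artefact of NJ on
#' non-additive input) are clamped to zero with a warning.
#'
#' @param d Symmetric distance matrix with at least 3 labels.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor-joining needs at least 3 labels")
  if (any(!is.finite(d))) stop("non-finite distances")
  tree <- ape::nj(stats::as.dist(d))
  if (any(tree$edge.length < 0)) {
    warning(sum(tree$edge.length < 0),
            " negative branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Serialize a tree to Newick text
#'
#' @param tree An `ape::phylo` tree, a `cub_dendrogram`, or an `hclust`.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  if (inherits(tree, "cub_dendrogram")) tree <- tree$phylo
  if (inherits(tree, "hclust")) tree <- ape::as.phylo(tree)
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
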