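#' Configuration for a full codon-usage-bias run
#'
#' @param input Path to a FASTA file of coding sequences, or `NULL` when
#'   `cohort` is given directly.
#' @param cohort A [cds_set()] (takes precedence over `input`).
#' @param samples Optional sample-sheet data frame (`id`, `species`,
#'   `group`) or path to a TSV with those columns.
#' @param ref_weights A [reference_weights()] object or path to a weight
#'   file; default the built-in E. coli table.
#' @param outdir Output directory (created if needed).
#' @param stages Character vector choosing analysis stages, any of
#'   `"composition"`, `"indices"`, `"rscu"`, `"selection"`,
#'   `"correlation"`, `"trees"`.
#' @param linkage Linkage for the RSCU dendrogram.
#' @param min_group_n Minimum group size for per-group correlation
#'   matrices (default 4).
#' @param seed Integer seed recorded in the manifest (analyses themselves
#'   are deterministic).
#' @return A list of class `cub_config`.
#' @export
cub_config <- function(input = NULL, cohort = NULL, samples = NULL,
                       ref_weights = NULL, outdir = "cub_out",
                       stages = c("composition", "indices", "rscu",
                                  "selection", "correlation", "trees"),
                       linkage = "average", min_group_n = 4L, seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(cohort) && is.null(input)) {
    stop("either 'input' (FASTA path) or 'cohort' (cds_set) is required")
  }
  if (is.character(samples)) {
    samples <- utils::read.delim(samples, stringsAsFactors = FALSE)
  }
  if (is.null(ref_weights)) {
    ref_weights <- default_reference_weights()
  } else if (is.character(ref_weights)) {
    ref_weights <- read_reference_weights(ref_weights)
  }
  structure(list(input = input, cohort = cohort, samples = samples,
                 ref_weights = ref_weights, outdir = outdir,
                 stages = stages, linkage = linkage,
                 min_group_n = as.integer(min_group_n),
                 seed = as.integer(seed)),
            class = "cub_config")
}

.write_tsv <- function(df, path, digits = NULL) {
  if (!is.null(digits)) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits = digits)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  path
}

#' Run the full codon-usage-bias pipeline
#'
#' Executes the requested stages on a cohort and writes their tables under
#' `outdir`: `composition.tsv` (2-decimal percent), `indices.tsv`
#' (3-decimal indices), `rscu_matrix.tsv` (59 codons x sequences, blanks
#' for undefined), `neutrality.tsv`, `pr2.tsv`, `enc_gc3.tsv`,
#' `correlation_<group>.tsv` (long format; one per sufficiently large
#' group plus `correlation_all.tsv`), `rscu_tree.nwk` + `rscu_leaf_order.txt`
#' and `cds_tree.nwk`, and a `manifest.json` recording the package
#' version, seed, stages and accumulated warnings. Per-sequence failures
#' are flagged, not fatal; outputs carry no timestamps so reruns are
#' byte-identical.
#'
#' @param config A [cub_config()].
#' @return Invisibly, a list of class `cub_pipeline` with the in-memory
#'   results (`cohort`, `composition`, `indices`, `rscu`, `neutrality`,
#'   `pr2`, `enc_gc3`, `correlations`, `rscu_tree`, `cds_tree`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cub_config"))
  cohort <- config$cohort
  if (is.null(cohort)) {
    cohort <- read_cds_fasta(config$input, samples = config$samples)
  } else if (!is.null(config$samples)) {
    m <- match(cohort$id, config$samples$id)
    if (anyNA(m)) stop("sample sheet missing ids: ",
                       paste(cohort$id[is.na(m)], collapse = ", "))
    cohort$species <- config$samples$species[m]
    cohort$group <- config$samples$group[m]
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  notes <- character(0)
  vw <- attr(cohort, "warnings")
  if (!is.null(vw)) {
    flagged <- vapply(vw, length, integer(1)) > 0
    notes <- c(notes, sprintf("%s: %s", names(vw)[flagged],
                              vapply(vw[flagged], paste,
                                     character(1), collapse = "; ")))
  }
  res <- list(cohort = cohort)
  has <- function(stage) stage %in% config$stages

  if (has("composition") || has("selection") || has("correlation")) {
    res$composition <- composition_table(cohort)
  }
  if (has("composition")) {
    .write_tsv(res$composition, file.path(config$outdir, "composition.tsv"),
               digits = 2)
  }
  if (has("indices") || has("correlation")) {
    res$indices <- index_table(cohort, ref = config$ref_weights)
    pr <- attr(res$indices, "problems")
    if (length(pr)) notes <- c(notes, sprintf("%s: %s", names(pr), pr))
  }
  if (has("indices")) {
    .write_tsv(as.data.frame(res$indices),
               file.path(config$outdir, "indices.tsv"), digits = 3)
  }
  if (has("rscu") || has("trees")) {
    res$rscu <- rscu_matrix(cohort)
  }
  if (has("rscu")) {
    m <- data.frame(codon = rownames(res$rscu),
                    aa = unname(genetic_code()$codon_to_aa[rownames(res$rscu)]),
                    res$rscu, check.names = FALSE)
    .write_tsv(m, file.path(config$outdir, "rscu_matrix.tsv"), digits = 3)
  }
  if (has("selection")) {
    grouped <- !all(is.na(cohort$group))
    sizes <- table(cohort$group)
    ok_groups <- names(sizes)[sizes >= 3L]
    neut_data <- res$composition
    if (grouped && length(ok_groups)) {
      dropped <- setdiff(names(sizes), ok_groups)
      if (length(dropped)) {
        notes <- c(notes, paste("neutrality: groups below 3 sequences",
                                "dropped:", paste(dropped, collapse = ", ")))
      }
      neut_data <- neut_data[neut_data$group %in% ok_groups, ]
    }
    res$neutrality <- neutrality_regression(
      neut_data, group = if (grouped) "group" else NULL)
    .write_tsv(as.data.frame(res$neutrality),
               file.path(config$outdir, "neutrality.tsv"))
    res$pr2 <- cbind(res$composition[, c("id", "species", "group")],
                     pr2_coordinates(res$composition)[, c("at_bias",
                                                          "gc_bias",
                                                          "quadrant")])
    .write_tsv(res$pr2, file.path(config$outdir, "pr2.tsv"), digits = 4)
    res$enc_gc3 <- enc_gc3_table(cohort)
    .write_tsv(res$enc_gc3, file.path(config$outdir, "enc_gc3.tsv"),
               digits = 4)
  }
  if (has("correlation")) {
    tab <- merge(res$composition[, c("id", "GC1", "GC2", "GC3", "GCs")],
                 as.data.frame(res$indices), by = "id")
    res$correlations <- list(all = spearman_matrix(tab))
    .write_tsv(correlation_long(res$correlations$all),
               file.path(config$outdir, "correlation_all.tsv"), digits = 4)
    for (grp in unique(stats::na.omit(cohort$group))) {
      sub <- tab[tab$id %in% cohort$id[cohort$group == grp], ]
      if (nrow(sub) < config$min_group_n) {
        notes <- c(notes, sprintf(
          "correlation: group %s skipped (%d < %d sequences)",
          grp, nrow(sub), config$min_group_n))
        next
      }
      res$correlations[[grp]] <- spearman_matrix(sub)
      .write_tsv(correlation_long(res$correlations[[grp]]),
                 file.path(config$outdir,
                           paste0("correlation_", grp, ".tsv")),
                 digits = 4)
    }
  }
  if (has("trees")) {
    d_rscu <- rscu_distance_matrix(res$rscu)
    res$rscu_tree <- hierarchical_cluster(d_rscu, linkage = config$linkage)
    write_newick(res$rscu_tree,
                 file.path(config$outdir, "rscu_tree.nwk"))
    writeLines(res$rscu_tree$leaf_order,
               file.path(config$outdir, "rscu_leaf_order.txt"))
    .write_tsv(data.frame(id = rownames(d_rscu), d_rscu,
                          check.names = FALSE),
               file.path(config$outdir, "rscu_distances.tsv"), digits = 4)
    d_cds <- pairwise_cds_distance(cohort)
    res$cds_tree <- withCallingHandlers(
      neighbor_joining(d_cds),
      warning = function(w) {
        notes <<- c(notes, paste("cds tree:", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    write_newick(res$cds_tree, file.path(config$outdir, "cds_tree.nwk"))
    .write_tsv(data.frame(id = rownames(d_cds), d_cds, check.names = FALSE),
               file.path(config$outdir, "cds_distances.tsv"), digits = 4)
  }
  res$manifest <- list(
    package = "cubkit",
    version = as.character(utils::packageVersion("cubkit")),
    seed = config$seed,
    stages = config$stages,
    n_sequences = nrow(cohort),
    linkage = config$linkage,
    reference = config$ref_weights$label,
    notes = notes
  )
  jsonlite::write_json(res$manifest,
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  class(res) <- "cub_pipeline"
  invisible(res)
}

#' @export
print.cub_pipeline <- function(x, ...) {
  cat("cubkit pipeline run:", x$manifest$n_sequences, "sequences; stages:",
      paste(x$manifest$stages, collapse = ", "), "\n")
  if (length(x$manifest$notes)) {
    cat("notes:\n")
    for (n in x$manifest$notes) cat(" -", n, "\n")
  }
  invisible(x)
}
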