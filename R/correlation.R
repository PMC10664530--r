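#' Spearman rank-correlation matrix across codon-usage quantities
#'
#' Pairwise Spearman correlations (average ranks on ties) with two-sided
#' p-values across the twelve per-sequence quantities conventionally
#' examined together: GC1, GC2, GC3, GCs, CAI, CBI, FOP, ENC, GRAVY,
#' AROMO, L_sym, L_aa. For n <= 9 the exact null distribution of the rank
#' statistic is used (falling back to the approximation when ties are
#' present); the asymptotic t approximation otherwise. Significance stars:
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.001 (no multiple-testing
#' correction). Constant columns yield undefined correlations, reported as
#' `NA`.
#'
#' @param data Data frame holding the variables, e.g. the merge of
#'   [composition_table()] and [index_table()].
#' @param vars Character vector of column names to correlate; defaults to
#'   the twelve standard quantities (intersected with what is present).
#' @param min_n Minimum number of rows (default 4).
#' @return An object of class `spearman_matrix`: list with symmetric
#'   matrices `rho` and `p`, character matrix `stars`, `n`, and `vars`.
#' @export
spearman_matrix <- function(data, vars = NULL, min_n = 4L) {
  default_vars <- c("GC1", "GC2", "GC3", "GCs", "CAI", "CBI", "FOP",
                    "ENC", "GRAVY", "AROMO", "L_sym", "L_aa")
  if (is.null(vars)) vars <- intersect(default_vars, names(data))
  stopifnot(length(vars) >= 2L, all(vars %in% names(data)))
  n <- nrow(data)
  if (n < min_n) {
    stop("need at least ", min_n, " rows for a correlation matrix, got ", n)
  }
  k <- length(vars)
  rho <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(rho) <- 1
  diag(p) <- 0
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      xi <- data[[vars[i]]]
      xj <- data[[vars[j]]]
      if (stats::var(xi) == 0 || stats::var(xj) == 0) next
      ct <- suppressWarnings(
        stats::cor.test(xi, xj, method = "spearman", exact = n <= 9L)
      )
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  stars <- matrix("", k, k, dimnames = list(vars, vars))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  diag(stars) <- ""
  structure(list(rho = rho, p = p, stars = stars, n = n, vars = vars),
            class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, digits = 2, ...) {
  cat("Spearman correlation matrix (n =", x$n, ")\n")
  shown <- matrix(paste0(formatC(x$rho, digits = digits, format = "f"),
                         x$stars),
                  nrow = length(x$vars),
                  dimnames = dimnames(x$rho))
  shown[is.na(x$rho)] <- "."
  print(noquote(shown))
  invisible(x)
}

#' Long-format view of a correlation matrix
#'
#' @param x A [spearman_matrix()] object.
#' @return Data frame with columns `var1`, `var2`, `rho`, `p`, `stars`
#'   (upper triangle only).
#' @export
correlation_long <- function(x) {
  stopifnot(inherits(x, "spearman_matrix"))
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  out <- data.frame(
    var1 = x$vars[idx[, 1]],
    var2 = x$vars[idx[, 2]],
    rho = x$rho[idx],
    p = x$p[idx],
    stars = x$stars[idx],
    stringsAsFactors = FALSE
  )
  out[order(out$var1, out$var2), , drop = FALSE]
}
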