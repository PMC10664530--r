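#' Neutrality regression of GC12 on GC3
#'
#' Ordinary least squares of GC12 (mean G+C at codon positions 1 and 2, the
#' response) on GC3 (predictor), per group, together with the Spearman rank
#' correlation of the same pairs. A slope near 1 indicates that a common
#' mutational GC pressure drives all codon positions; a slope near 0 (no
#' correlation) indicates that selection holds positions 1-2 while position
#' 3 drifts.
#'
#' @param data Data frame containing the GC12 and GC3 columns (percent or
#'   fraction, used as given), e.g. the output of [composition_table()].
#' @param gc12,gc3 Column names (defaults `"GC12"`, `"GC3"`).
#' @param group Optional column name holding group labels; when `NULL` all
#'   rows form one group.
#' @param min_n Minimum points per group (default 3); smaller groups raise
#'   an error.
#' @return A data frame of class `cub_neutrality` with one row per group:
#'   `group`, `n`, `slope`, `intercept`, `r_squared`, `spearman_rho`,
#'   `p_spearman`, `p_ols`. The fitted points are kept in the `"points"`
#'   attribute for plotting.
#' @export
neutrality_regression <- function(data, gc12 = "GC12", gc3 = "GC3",
                                  group = NULL, min_n = 3L) {
  stopifnot(is.data.frame(data), gc12 %in% names(data), gc3 %in% names(data))
  g <- if (is.null(group)) rep("all", nrow(data)) else as.character(data[[group]])
  pieces <- split(seq_len(nrow(data)), g)
  rows <- lapply(names(pieces), function(lab) {
    idx <- pieces[[lab]]
    x <- data[[gc3]][idx]
    y <- data[[gc12]][idx]
    if (length(idx) < min_n) {
      stop("group '", lab, "' has ", length(idx),
           " points; at least ", min_n, " required")
    }
    if (stats::var(x) == 0) {
      stop("group '", lab, "': GC3 has zero variance, slope undefined")
    }
    fit <- stats::lm(y ~ x)
    sm <- suppressWarnings(summary(fit))  # perfect fits are legitimate here
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = length(idx) <= 9L)
    )
    data.frame(
      group = lab, n = length(idx),
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = sm$r.squared,
      spearman_rho = unname(ct$estimate),
      p_spearman = ct$p.value,
      p_ols = sm$coefficients[2, 4],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cub_neutrality", "data.frame")
  attr(out, "points") <- data.frame(group = g, GC3 = data[[gc3]],
                                    GC12 = data[[gc12]])
  out
}

#' @export
print.cub_neutrality <- function(x, digits = 4, ...) {
  cat("Neutrality regression (GC12 ~ GC3)\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], signif, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @describeIn neutrality_regression Scatter plot with per-group fit lines
#'   and the identity line.
#' @param x A `cub_neutrality` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cub_neutrality <- function(x, ...) {
  pts <- attr(x, "points")
  cols <- stats::setNames(seq_along(x$group), x$group)
  graphics::plot(pts$GC3, pts$GC12, col = cols[pts$group], pch = 19,
                 xlab = "GC3 (%)", ylab = "GC12 (%)", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  for (i in seq_len(nrow(x))) {
    graphics::abline(x$intercept[i], x$slope[i], col = cols[x$group[i]])
  }
  graphics::legend("topleft", legend = x$group, col = cols, pch = 19,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Parity-rule-2 bias coordinates
#'
#' PR2 coordinates of a sequence's third-position composition:
#' `at_bias = A3 / (A3 + T3)` and `gc_bias = G3 / (G3 + C3)`. Under parity
#' (A = T and G = C at position 3) both equal 0.5, the centre of the PR2
#' plot; displacement from the centre gives the direction and degree of
#' bias. Quadrants are labelled by the preferred bases (1: A and G, 2: A
#' and C, 3: T and C, 4: T and G).
#'
#' @param comp A `position_composition` vector, or a data frame with
#'   columns A3, T3, G3, C3 (e.g. from [composition_table()]).
#' @return A data frame with columns `at_bias`, `gc_bias`, `quadrant`
#'   (plus `id` when present in the input).
#' @export
pr2_coordinates <- function(comp) {
  if (!is.data.frame(comp)) {
    comp <- as.data.frame(as.list(unclass(comp)))
  }
  stopifnot(all(c("A3", "T3", "G3", "C3") %in% names(comp)))
  at_den <- comp$A3 + comp$T3
  gc_den <- comp$G3 + comp$C3
  if (any(at_den == 0) || any(gc_den == 0)) {
    stop("PR2 coordinates undefined: zero A3+T3 or G3+C3 denominator")
  }
  at <- comp$A3 / at_den
  gc <- comp$G3 / gc_den
  quadrant <- ifelse(
    at == 0.5 & gc == 0.5, "center",
    ifelse(at > 0.5,
           ifelse(gc > 0.5, "1 (A/G)", "2 (A/C)"),
           ifelse(gc > 0.5, "4 (T/G)", "3 (T/C)"))
  )
  out <- data.frame(at_bias = at, gc_bias = gc, quadrant = quadrant,
                    stringsAsFactors = FALSE)
  if ("id" %in% names(comp)) out <- cbind(comp["id"], out)
  rownames(out) <- NULL
  out
}

#' Wright's expected ENC under pure GC3 drift
#'
#' The null curve relating ENC to the third-position G+C fraction `s` when
#' composition alone (no selection among synonymous codons beyond the GC
#' pressure) shapes usage:
#' `ENC = 2 + s + 29 / (s^2 + (1 - s)^2)`.
#'
#' @param s GC3 as a fraction in `[0, 1]` (vectorised).
#' @return Expected ENC values; 60.5 at s = 0.5, 31 at s = 0, 32 at s = 1.
#' @export
enc_expected <- function(s) {
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1)) {
    stop("GC3 fraction must lie in [0, 1]")
  }
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Relative deviation of observed ENC from the null curve
#'
#' `(expected - observed) / expected`; positive values place the point
#' below the curve, the classic signature of selection on codon usage.
#'
#' @param observed_enc Observed ENC value(s).
#' @param gc3 GC3 fraction(s) in `[0, 1]`.
#' @return Relative deviation(s).
#' @export
enc_deviation <- function(observed_enc, gc3) {
  expected <- enc_expected(gc3)
  (expected - observed_enc) / expected
}

#' ENC-GC3 table for a cohort
#'
#' Per-sequence observed ENC, GC3, the expected ENC under pure GC3 drift,
#' and the relative deviation from the curve.
#'
#' @param x A [cds_set()].
#' @return A data frame with columns `id`, `species`, `group`, `GC3`
#'   (fraction), `ENC`, `ENC_expected`, `deviation`.
#' @export
enc_gc3_table <- function(x) {
  stopifnot(inherits(x, "cds_set"))
  rows <- lapply(x$seq, function(s) {
    counts <- count_codons(s, validated = TRUE)
    gc3 <- unclass(position_composition(counts))[["GC3"]] / 100
    e <- as.numeric(enc(counts))
    c(GC3 = gc3, ENC = e, ENC_expected = enc_expected(gc3),
      deviation = enc_deviation(e, gc3))
  })
  out <- cbind(x[, c("id", "species", "group")],
               as.data.frame(do.call(rbind, rows)))
  rownames(out) <- NULL
  out
}

#' ENC-GC3 scatter plot with the null curve
#'
#' @param tab Output of [enc_gc3_table()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_enc_gc3 <- function(tab, ...) {
  graphics::plot(100 * tab$GC3, tab$ENC, pch = 19,
                 xlab = "GC3 (%)", ylab = "ENC",
                 xlim = c(0, 100), ylim = c(20, 62), ...)
  s <- seq(0.01, 0.99, length.out = 200)
  graphics::lines(100 * s, enc_expected(s), col = "grey40")
  invisible(tab)
}
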