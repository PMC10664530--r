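#' Specification for a synthetic CDS cohort
#'
#' Describes an i.i.d. cohort of in-frame coding sequences: amino acids are
#' drawn from `aa_frequencies`, the codon for each amino acid from a
#' per-family distribution. The family distributions are controlled by two
#' dials: `codon_preference`, a scalar strength in `[0, 1]` interpolating
#' from uniform family usage (0, ENC near 61) to a single codon per family
#' (1, ENC exactly 20) -- or an explicit list of per-family probability
#' vectors; and `gc3_target`, which tilts every family distribution
#' towards G/C-ending codons by a common exponential factor solved so that
#' the expected third-position G+C over the synonymous set hits the
#' target.
#'
#' @param n_sequences Number of sequences.
#' @param length_aa Codons per sequence: a single value or a `c(min, max)`
#'   range sampled uniformly.
#' @param aa_frequencies Named distribution over the 20 amino acids
#'   (one-letter code); default uniform. Need not be normalised.
#' @param codon_preference Scalar strength in `[0, 1]`, or a named list of
#'   per-amino-acid probability vectors over the family codons.
#' @param preferred_codons Named character vector, amino acid -> the codon
#'   a scalar `codon_preference` concentrates on; default
#'   [default_preferred_codons()].
#' @param gc3_target Target third-position G+C fraction in (0, 1), or
#'   `NULL` to leave families untilted.
#' @param group Group label attached to every sequence.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_sequences, length_aa, aa_frequencies = NULL,
                           codon_preference = 0, preferred_codons = NULL,
                           gc3_target = NULL, group = "synthetic",
                           seed = 1L) {
  code <- genetic_code()
  aa20 <- setdiff(sort(unique(unname(code$codon_to_aa))), "*")
  if (is.null(aa_frequencies)) {
    aa_frequencies <- stats::setNames(rep(1, length(aa20)), aa20)
  }
  stopifnot(all(names(aa_frequencies) %in% aa20),
            all(aa_frequencies >= 0), sum(aa_frequencies) > 0)
  aa_frequencies <- aa_frequencies / sum(aa_frequencies)
  stopifnot(length(length_aa) %in% c(1L, 2L), all(length_aa >= 1))
  if (is.null(preferred_codons)) preferred_codons <- default_preferred_codons()
  if (is.numeric(codon_preference)) {
    stopifnot(length(codon_preference) == 1L,
              codon_preference >= 0, codon_preference <= 1)
  } else {
    stopifnot(is.list(codon_preference),
              all(names(code$families) %in% names(codon_preference)))
  }
  if (!is.null(gc3_target)) {
    stopifnot(gc3_target > 0, gc3_target < 1)
  }
  structure(
    list(n_sequences = as.integer(n_sequences),
         length_aa = as.integer(length_aa),
         aa_frequencies = aa_frequencies,
         codon_preference = codon_preference,
         preferred_codons = preferred_codons,
         gc3_target = gc3_target,
         group = group, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Default preferred codon per family
#'
#' The codon a scalar preference strength concentrates usage on:
#' alphabetically first within each family (a fixed, arbitrary convention;
#' supply `preferred_codons` to [synthetic_spec()] to override).
#'
#' @return Named character vector, amino acid -> codon.
#' @export
default_preferred_codons <- function() {
  code <- genetic_code()
  vapply(code$families, function(fam) fam[[1]], character(1))
}

## G+C indicator for third positions of a codon vector.
.gc3_of <- function(codons) as.numeric(substr(codons, 3, 3) %in% c("G", "C"))

#' Per-family codon distributions implied by a synthetic spec
#'
#' Resolves the preference and GC3-tilt dials into explicit per-amino-acid
#' codon probabilities. These are the distributions the generator draws
#' from, and their implied RSCU (`probability * degeneracy`) is the
#' recovery target for parameter-recovery checks.
#'
#' @param spec A [synthetic_spec()].
#' @return Named list of probability vectors over each family's codons,
#'   with attribute `"tilt"` (the fitted G/C multiplier, 1 when no target).
#' @export
codon_distributions <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  code <- genetic_code()
  base <- lapply(names(code$families), function(aa) {
    fam <- code$families[[aa]]
    if (is.list(spec$codon_preference)) {
      p <- spec$codon_preference[[aa]]
      stopifnot(length(p) == length(fam), all(p >= 0), sum(p) > 0)
      if (is.null(names(p))) names(p) <- fam
      p[fam] / sum(p)
    } else {
      theta <- spec$codon_preference
      u <- stats::setNames(rep(1 / length(fam), length(fam)), fam)
      point <- stats::setNames(as.numeric(fam == spec$preferred_codons[[aa]]),
                               fam)
      (1 - theta) * u + theta * point
    }
  })
  names(base) <- names(code$families)
  tilt <- 1
  if (!is.null(spec$gc3_target)) {
    ## amino-acid weights over the synonymous families only
    f_syn <- spec$aa_frequencies[names(code$families)]
    f_syn[is.na(f_syn)] <- 0
    if (sum(f_syn) == 0) stop("gc3_target set but no synonymous amino acids")
    f_syn <- f_syn / sum(f_syn)
    exp_gc3 <- function(log_t) {
      t <- exp(log_t)
      sum(vapply(names(base), function(aa) {
        p <- base[[aa]] * t^.gc3_of(names(base[[aa]]))
        f_syn[[aa]] * sum(p * .gc3_of(names(p))) / sum(p)
      }, numeric(1)))
    }
    lo <- exp_gc3(-30); hi <- exp_gc3(30)
    if (spec$gc3_target < lo || spec$gc3_target > hi) {
      stop(sprintf(
        "gc3_target %.3f infeasible: achievable range is [%.3f, %.3f]",
        spec$gc3_target, lo, hi))
    }
    root <- stats::uniroot(function(lt) exp_gc3(lt) - spec$gc3_target,
                           lower = -30, upper = 30, tol = 1e-12)
    tilt <- exp(root$root)
    base <- lapply(base, function(p) {
      p <- p * tilt^.gc3_of(names(p))
      p / sum(p)
    })
  }
  attr(base, "tilt") <- tilt
  base
}

#' Generate a synthetic CDS cohort
#'
#' Draws each sequence amino acid by amino acid from the spec's
#' frequencies and codon by codon from the resolved family distributions
#' ([codon_distributions()]); Met and Trp are emitted as ATG / TGG. Stop
#' codons are never generated internally; a single terminal TAA is
#' appended (and stripped again by validation, exercising the validator).
#' A single seeded stream drives the cohort, with per-sequence substreams
#' derived deterministically so regeneration is reproducible.
#'
#' @param spec A [synthetic_spec()].
#' @return A [cds_set()] with attributes `"draw_log"` (named list of
#'   per-sequence 64-codon realised count vectors), `"distributions"` (the
#'   resolved family distributions) and `"spec"`.
#' @export
generate_cds <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  code <- genetic_code()
  dists <- codon_distributions(spec)
  single <- c(M = "ATG", W = "TGG")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  sub_seeds <- sample.int(.Machine$integer.max, spec$n_sequences)
  seqs <- character(spec$n_sequences)
  log <- vector("list", spec$n_sequences)
  aa_pool <- names(spec$aa_frequencies)
  for (i in seq_len(spec$n_sequences)) {
    set.seed(sub_seeds[i])
    L <- if (length(spec$length_aa) == 2L) {
      sample(seq.int(spec$length_aa[1], spec$length_aa[2]), 1L)
    } else spec$length_aa
    aas <- sample(aa_pool, L, replace = TRUE, prob = spec$aa_frequencies)
    codons <- character(L)
    for (aa in unique(aas)) {
      idx <- which(aas == aa)
      if (aa %in% names(single)) {
        codons[idx] <- single[[aa]]
      } else {
        p <- dists[[aa]]
        codons[idx] <- sample(names(p), length(idx), replace = TRUE,
                              prob = p)
      }
    }
    seqs[i] <- paste(c(codons, "TAA"), collapse = "")
    tab <- table(factor(codons, levels = names(code$codon_to_aa)))
    log[[i]] <- stats::setNames(as.integer(tab), names(tab))
  }
  ids <- sprintf("%s_%02d", spec$group, seq_len(spec$n_sequences))
  out <- cds_set(ids, seqs, species = ids, group = spec$group)
  names(log) <- ids
  attr(out, "draw_log") <- log
  attr(out, "distributions") <- dists
  attr(out, "spec") <- spec
  out
}

## Row-bind cds_sets, concatenating draw logs.
combine_cds_sets <- function(sets) {
  out <- do.call(rbind, lapply(sets, as.data.frame))
  out <- cds_set(out$id, out$seq, species = out$species, group = out$group,
                 validate = FALSE)
  attr(out, "draw_log") <- do.call(c, lapply(sets, attr, "draw_log"))
  out
}

#' Amino-acid and codon weights under a mutational GC pressure
#'
#' The codon distribution implied by independent base draws with
#' `P(G) = P(C) = g / 2` and `P(A) = P(T) = (1 - g) / 2` at every codon
#' position. Used to build "pure mutation" cohorts in which GC12 and GC3
#' are driven by the same pressure.
#'
#' @param g G+C pressure in (0, 1).
#' @return List with `aa_frequencies` (over the 20 amino acids) and
#'   `codon_preference` (per-family conditional distributions), ready for
#'   [synthetic_spec()].
#' @export
mutation_pressure_profile <- function(g) {
  stopifnot(g > 0, g < 1)
  code <- genetic_code()
  p_base <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
  codon_w <- vapply(names(code$codon_to_aa), function(cod) {
    prod(p_base[strsplit(cod, "")[[1]]])
  }, numeric(1))
  aa20 <- setdiff(sort(unique(unname(code$codon_to_aa))), "*")
  aa_freq <- vapply(aa20, function(a) {
    sum(codon_w[code$codon_to_aa == a])
  }, numeric(1))
  fam_dist <- lapply(code$families, function(fam) codon_w[fam] / sum(codon_w[fam]))
  list(aa_frequencies = aa_freq / sum(aa_freq),
       codon_preference = fam_dist)
}

#' Cohort with a gradient of GC3 pressures
#'
#' Each sequence gets its own GC pressure drawn uniformly from
#' `gc3_range`. In `"mutation"` mode the pressure shapes all three codon
#' positions (via [mutation_pressure_profile()]), so GC12 tracks GC3 and
#' the neutrality slope approaches 1. In `"selection"` mode amino-acid
#' usage is held fixed (uniform) while only third positions are tilted to
#' the pressure, pinning GC12 and driving the slope to 0.
#'
#' @param n Number of sequences.
#' @param mode `"mutation"` or `"selection"`.
#' @param gc3_range Range of pressures.
#' @param length_aa Codons per sequence.
#' @param seed Integer seed.
#' @return A [cds_set()] with attribute `"gc_pressure"` (the per-sequence
#'   drawn pressures).
#' @export
generate_gradient_cohort <- function(n = 50L,
                                     mode = c("mutation", "selection"),
                                     gc3_range = c(0.2, 0.8),
                                     length_aa = 300L, seed = 1L) {
  mode <- match.arg(mode)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  g <- stats::runif(n, gc3_range[1], gc3_range[2])
  sub_seeds <- sample.int(.Machine$integer.max, n)
  sets <- lapply(seq_len(n), function(i) {
    spec <- if (mode == "mutation") {
      prof <- mutation_pressure_profile(g[i])
      synthetic_spec(1L, length_aa,
                     aa_frequencies = prof$aa_frequencies,
                     codon_preference = prof$codon_preference,
                     group = sprintf("seq%03d", i), seed = sub_seeds[i])
    } else {
      synthetic_spec(1L, length_aa, gc3_target = g[i],
                     group = sprintf("seq%03d", i), seed = sub_seeds[i])
    }
    generate_cds(spec)
  })
  out <- combine_cds_sets(sets)
  out$group <- mode
  attr(out, "gc_pressure") <- g
  out
}

#' Synthetic cohort emulating an apicomplexan thioredoxin study design
#'
#' 32 sequences in the six groups used for grouped codon-usage analyses of
#' apicomplexan parasites: AT-rich Cryptosporidium-like (4) and
#' Plasmodium-like (9) groups, GC-rich Babesia-like (4), Eimeria-like (5)
#' and mixed "Other" (6) groups, and an intermediate Theileria-like group
#' (4). Lengths are drawn uniformly between 85 and 555 codons (255-1665
#' nt), the span typical of thioredoxin coding sequences; group GC3
#' targets (0.20-0.65) and moderate codon-preference strengths reproduce
#' the AT-ended versus GC-ended contrast such cohorts show.
#'
#' @param seed Integer seed.
#' @return A [cds_set()] of 32 sequences with group labels Babesia,
#'   Cryptosporidium, Eimeria, Plasmodium, Theileria, Other.
#' @export
generate_apicomplexan_cohort <- function(seed = 1L) {
  design <- data.frame(
    group = c("Babesia", "Cryptosporidium", "Eimeria", "Plasmodium",
              "Theileria", "Other"),
    n = c(4L, 4L, 5L, 9L, 4L, 6L),
    gc3 = c(0.62, 0.25, 0.65, 0.20, 0.45, 0.60),
    theta = c(0.25, 0.25, 0.30, 0.30, 0.15, 0.25),
    stringsAsFactors = FALSE
  )
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, nrow(design))
  sets <- lapply(seq_len(nrow(design)), function(i) {
    spec <- synthetic_spec(
      n_sequences = design$n[i],
      length_aa = c(85L, 555L),
      codon_preference = design$theta[i],
      gc3_target = design$gc3[i],
      group = design$group[i],
      seed = sub_seeds[i]
    )
    generate_cds(spec)
  })
  combine_cds_sets(sets)
}
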