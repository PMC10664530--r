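---
title: "Codon usage bias analysis with cubkit: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias analysis with cubkit: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cubkit analyses codon usage bias (CUB) in cohorts of protein-coding
sequences: the unequal use of synonymous codons that arises from the
interplay of mutational pressure (what the genome's base composition makes
common) and natural selection (what translation favours). The package
implements the per-sequence statistics and cohort-level diagnostics used
throughout the CUB literature, with a seeded synthetic-sequence generator
so that every estimator can be checked against known truth. This vignette
records the methods, the defaults, and the reasoning behind the design
choices where the conventions in the field are genuinely open.

```{r setup}
library(cubkit)
```

## The 59-codon synonymous frame

All bias statistics are computed over the 59 *synonymous* codons: the 61
sense codons minus ATG (Met) and TGG (Trp), whose amino acids admit no
synonymous choice, with the three stop codons excluded as well. These 59
codons encode 18 amino acids in families of degeneracy 2, 3, 4 and 6.
Two lengths summarise a sequence: `L_aa`, the number of translatable
codons (Met and Trp included), and `L_sym <= L_aa`, the number of codons
inside the synonymous set.

Composition statistics (`position_composition()`) follow the same
restriction: A3/T3/G3/C3 are percentages of third-position bases among
synonymous codons only, and GC1/GC2/GC3 are the G+C percentages at each
codon position of those codons. `GC12` is the arithmetic mean of GC1 and
GC2. `GCs` is the direct G+C count over all three positions; because each
position contributes exactly one base per codon, this equals the mean of
GC1, GC2 and GC3 — the two candidate definitions coincide under the
59-codon restriction, which is why the package does not offer a switch.

Validation (`validate_cds()`) is deliberately forgiving by default:
a trailing partial codon is trimmed with a warning, codons containing
ambiguous bases (GenBank CDSs occasionally contain Ns) are dropped with a
warning, one terminal stop codon is stripped, and internal stop codons
warn without aborting — a pseudogene guard, since a single frameshifted
record should flag its row rather than kill a cohort run. A `strict`
policy turns the frame repair into an error.

## Per-sequence indices

**RSCU.** For codon $c$ of an amino acid with family total $n_{aa}$ and
degeneracy $k$, $\mathrm{RSCU}_c = n_c / (n_{aa}/k)$: 1 means unbiased
usage, $k$ means the codon carries the whole family. Codons of amino
acids absent from a sequence are *undefined* (`NA`), not zero — a zero
would claim maximal avoidance on no evidence, and would fabricate
dissimilarity in downstream clustering.

**ENC** (effective number of codons, `enc()`). Per amino acid used
$n \ge 2$ times, the homozygosity is
$F = (n \sum_i p_i^2 - 1)/(n - 1)$; $F$ is averaged within each
degeneracy class and
$\mathrm{ENC} = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$,
from 20 (one codon per amino acid) to 61 (uniform usage). Two practical
conventions are needed where the estimator is silent:

* *Missing classes.* Short sequences can leave a degeneracy class with no
  amino acid observed twice. The 3-fold class (Ile alone) is imputed on
  the inverse scale, $1/\bar F_3$ = the mean of $1/\bar F_2$ and
  $1/\bar F_4$; any other missing class takes the mean $\bar F$ of the
  nearest originally-defined classes. Imputing from the *original*
  estimates keeps the result independent of imputation order.
* *Clamping.* The small-sample correction makes finite uniform usage
  estimate slightly above 61; estimates are clamped to 61 (the raw value
  is kept in the `"raw"` attribute).

**CAI / CBI / FOP** all depend on a reference set of relative
adaptiveness weights $w_c \in (0, 1]$ with the family maximum at 1. CAI
is the count-weighted geometric mean of $w$; CBI is
$(N_{opt} - N_{ran})/(N_{tot} - N_{ran})$, with $N_{ran} = \sum
n_{aa}/k$ the optimal count expected under uniform usage; FOP is
$N_{opt}/N_{tot}$. FOP is implemented on its mathematical range
$[0, 1]$ (reported empirical lower bounds around 0.36 describe data, not
the statistic). The package ships the classic highly-expressed
*E. coli* reference table as its default — the de-facto default of
long-standing codon-usage software — but these three indices are only
interpretable *relative to their reference*: cross-tool comparisons
require the matched table, supplied via `reference_weights()` or
`read_reference_weights()`. When weights are derived from a reference
count table (`compute_reference_weights()`), unobserved codons receive a
0.5 pseudo-count so that all weights stay positive and CAI's logarithm
is defined.

**GRAVY** is the mean Kyte–Doolittle hydropathy of the translated
protein (positive = hydrophobic); **AROMO** the fraction of Phe/Tyr/Trp
residues. Both summarise amino-acid composition, whose variation
confounds pure codon-level signals, which is why they sit alongside the
codon indices in the correlation analysis.

## Mutation-versus-selection diagnostics

**Neutrality regression** (`neutrality_regression()`): ordinary least
squares of GC12 on GC3, per group, plus the Spearman correlation of the
same pairs. Under a shared mutational GC pressure all positions drift
together and the slope approaches 1; when selection pins the
amino-acid-determined positions 1–2 while position 3 drifts, the slope
approaches 0. Significance is reported from the Spearman test (the
conventional choice for these small grouped cohorts, making no linearity
assumption), with the OLS p-value also emitted. Groups need at least 3
points; zero GC3 variance is an error rather than a silent `NA`.

**PR2 bias** (`pr2_coordinates()`): $A_3/(A_3+T_3)$ against
$G_3/(G_3+C_3)$. Under parity rule 2 (no strand/selection asymmetry)
both are 0.5. Coordinates are computed from the full synonymous-set
third-position counts — the same quantities the composition table
reports — so the PR2 plot and the composition table cannot disagree;
a fourfold-family-only variant common in some tools is easy to compute
from `count_codons()` output but is not the default.

**ENC–GC3** (`enc_expected()`, `enc_deviation()`): Wright's null curve
$\mathrm{ENC} = 2 + s + 29/(s^2 + (1-s)^2)$ gives the ENC expected when
composition alone (third-position G+C fraction $s$) drives usage.
`enc_deviation()` reports $(\text{expected} - \text{observed}) /
\text{expected}$, positive below the curve — the classic selection
signature. The curve is an approximation: it treats all degeneracy
classes through the two-fold homozygosity form, and for cohorts
generated under pure GC3 drift the exact expectation sits up to about
one ENC unit above the curve at strongly AT- or GC-rich compositions.
Tests therefore check that drift cohorts straddle the curve *on
average* (mean absolute gap under 2 ENC units, mean relative deviation
near zero) rather than demanding every point within a fixed band, and
that increasing codon-preference strength moves cohorts strictly below.

## Correlation analysis

`spearman_matrix()` correlates the twelve per-sequence quantities (GC1,
GC2, GC3, GCs, CAI, CBI, FOP, ENC, GRAVY, AROMO, L_sym, L_aa) with
Spearman's rank method, average ranks on ties. For groups of up to 9
sequences the exact null distribution of the rank statistic is used
(falling back to the approximation when ties make the exact distribution
unavailable); larger groups use the asymptotic approximation. Stars mark
p < 0.05 / 0.01 / 0.001 with no multiple-testing correction — the
conventional presentation for these index matrices, to be read as
descriptive annotation rather than confirmatory inference. Constant
columns yield undefined correlations and are reported blank.

## Trees

Two complementary views of a cohort's structure:

* **RSCU clustering**: squared-Euclidean distances between RSCU
  profiles, summed over the codons defined in *both* sequences
  (pairwise-complete deletion), then agglomerative clustering
  (`hierarchical_cluster()`). Average linkage is the default — the
  distance is what the analysis specifies; linkage is a presentation
  choice, and average linkage is the least shape-assuming of the
  standard options ("ward" maps to `ward.D`, appropriate because the
  distances are already squared). Tie-breaking is deterministic (lowest
  index), so permuting the input cannot change the topology. The leaf
  order is exported for heatmap reuse.
* **CDS tree**: global pairwise alignment (match +1, mismatch −1, gap
  open −5, gap extend −1 — strongly gap-averse defaults appropriate for
  homologous in-frame CDSs; all four scores are arguments), p-distances
  over aligned non-gap columns, then neighbor-joining. NJ on additive
  distances recovers the generating tree exactly; on real (non-additive)
  distances it can produce slightly negative branch lengths, which are
  clamped to zero with a warning. Trees serialise to Newick via
  `write_newick()`.

RSCU-based and sequence-based trees answer different questions — codon
*usage* similarity versus sequence descent — and the package treats
their comparison as an output of interest, not a consistency check.

## The synthetic generator

`generate_cds()` draws i.i.d. sequences from an explicit model: amino
acids from `aa_frequencies`, codons from per-family distributions
controlled by two dials. `codon_preference` $\theta \in [0, 1]$
interpolates linearly from uniform family usage ($\theta = 0$, ENC near
61) to a single codon per family ($\theta = 1$, ENC exactly 20).
`gc3_target` multiplies every G/C-ending codon's probability by a common
factor $t$, with $t$ solved (by `uniroot`, to machine precision on the
expectation) so the expected synonymous-set GC3 equals the target;
targets outside the achievable range for the given family distributions
raise an infeasibility error rather than silently saturating. The
resolved distributions are returned, and their implied RSCU
($p_c \times k$) is the recovery target in tests. Stop codons are never
generated internally; one terminal stop is appended and then stripped by
validation, so the validator is exercised on every synthetic cohort.
A single seed drives a cohort, with per-sequence sub-seeds drawn up
front so partial regeneration is reproducible.

Two cohort builders encode study designs:

* `generate_gradient_cohort()` gives each sequence its own GC pressure
  drawn from a range. In `"mutation"` mode the pressure shapes all three
  codon positions (amino-acid frequencies and family distributions both
  follow independent base draws at that pressure), so GC12 tracks GC3
  and the neutrality slope approaches 1; in `"selection"` mode
  amino-acid usage is fixed while only third positions are tilted, so
  GC12 is pinned and the slope approaches 0. Recovery is checked at 50
  sequences of 300 codons with a ±0.2 band around the target slopes,
  sized for the sampling noise of cohorts of that size.
* `generate_apicomplexan_cohort()` emulates a 32-sequence, six-group
  parasite thioredoxin study design: AT-rich Cryptosporidium-like (4)
  and Plasmodium-like (9) groups at GC3 targets 0.25 and 0.20, GC-rich
  Babesia-like (4), Eimeria-like (5) and mixed "Other" (6) groups at
  0.62, 0.65 and 0.60, and an intermediate Theileria-like group (4) at
  0.45, with moderate preference strengths (0.15–0.30) and lengths
  uniform between 85 and 555 codons (255–1665 nt). The targets were
  chosen once to reproduce the qualitative AT-ended versus GC-ended
  contrast and the GC3 span (roughly 12–86%) typical of such cohorts.

What the generator does **not** emulate: phylogenetic correlation
(sequences are i.i.d. given group parameters, with no substitution
process along a tree), amino-acid composition differences tied to
protein function, context effects (dinucleotide or codon-pair biases),
and length–expression covariation. Passing recovery tests therefore
shows the estimators are correct *given the model*, not that real
cohorts satisfy the model; on real data the diagnostics remain what they
are in the literature — descriptive evidence, not formal tests of
selection.

## Numerical conventions and check sizes

Full precision is kept internally everywhere; rounding (2 decimals for
composition percentages, 3 for indices, 4 for diagnostic tables) happens
only in printed and written tables. Pipeline outputs carry no
timestamps, so reruns of the same configuration are byte-identical.
Degenerate inputs fail loudly at the per-sequence level (no synonymous
codons, empty sequence after cleaning, undefined ENC) and are collected
as flagged rows at the cohort level.

The test suite validates every index against independent brute-force
recomputation (tolerance 1e-9 on 20 random sequences), boundary cases in
closed form, and parameter recovery at sizes chosen to make sampling
noise small relative to the tolerance: GC3 within 1–2 percentage points
at 10,000 codons; pooled RSCU within 0.1 per codon at 10 × 10,000
codons; neutrality slopes at 50 sequences; 100 random additive trees of
up to 8 taxa recovered exactly by NJ. The acceptance script
(`scripts/acceptance.R`) recomputes the same classes of quantities from
scratch at a given seed.

## Limitations

* CAI, CBI and FOP values are reference-relative; with the default
  *E. coli* table they rank sequences consistently but are not
  comparable to values computed under another tool's reference without
  supplying the matched table.
* ENC on very short sequences (tens of codons) relies on the
  missing-class imputation and is noisy; treat per-sequence ENC below
  ~100 synonymous codons with caution.
* p-distances with fixed alignment scores are a deliberately simple
  distance for NJ; no substitution-model correction (K2P/GTR) is
  offered, and no bootstrap support is computed.
* The three selection diagnostics are graphical conventions of the CUB
  literature, not likelihood-based decompositions of mutation and
  selection.
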