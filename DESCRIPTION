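Package: cubkit
Title: Codon Usage Bias Analysis for Coding-Sequence Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing codon usage bias in cohorts of protein-coding
    sequences, in the style of classic codon-usage software. Computes per-position
    nucleotide composition over the 59 synonymous codons, relative synonymous codon
    usage (RSCU), the effective number of codons (ENC), the codon adaptation index
    (CAI), the codon bias index (CBI), the frequency of optimal codons (FOP),
    hydropathy (GRAVY) and aromaticity; mutation-versus-selection diagnostics
    (neutrality regression of GC12 on GC3, parity-rule-2 bias coordinates, the
    ENC-GC3 null curve); Spearman rank-correlation matrices across indices;
    RSCU-based hierarchical clustering and neighbor-joining trees from pairwise
    coding-sequence distances; and a seeded synthetic-CDS generator with
    controllable GC3 and codon-preference strength so every stage of the analysis
    can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ape,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
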