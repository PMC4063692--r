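Package: evemine
Title: Discovery and Dating of Endogenous Herpesvirus-Like Elements in
    Draft Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Paleovirological analysis of draft genome assemblies:
    six-frame translated homology search with shortlist filtering and
    reciprocal best-hit classification; detection of telomeric hexamer
    repeat (TMR) arrays and host/virus junction calling; molecular
    dating of endogenous insertions from the maximum-likelihood GTR
    divergence of a TMR array relative to its hypothetical perfect-repeat
    ancestor, converted to time without halving; coding-degradation
    profiling (premature stops, frameshifts) and endogenous-versus-
    exogenous provenance classification; mate-pair-guided iterative
    contig edge extension and targeted scaffolding; and per-contig
    nucleotide-composition PCA with a permutation outlier assessment.
    Includes a synthetic genome generator (neutrally evolved viral
    insertion across a telomeric junction, simulated read pairs,
    repeat-driven assembly fragmentation) providing ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
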