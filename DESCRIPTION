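Package: metapang
Title: Metapangenomics of Depth-Stratified Microbial Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A workflow for metapangenomic inference on incomplete microbial
    genome collections: fragment-based average nucleotide identity (ANI) and
    95% population-genome binning, CD-HIT-style greedy gene-catalog
    dereplication, protein similarity graphs filtered with the minbit
    heuristic and clustered into orthogroups by Markov clustering (MCL),
    metagenomic read recruitment at identity/coverage thresholds with
    per-gene, per-orthogroup and per-population coverage profiles across
    depth-resolved samples, and ecotype delineation from the congruence of
    ANI subclades and depth distributions. Includes a synthetic stratified
    community generator with planted truth (subclades, orthofamilies,
    depth-dependent abundance, incomplete genomes, error-bearing reads) so
    the whole inference chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
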