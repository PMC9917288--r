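Package: serpinome
Title: Structural Curation, Homeology and Expression Profiling of Polyploid
    Serpin Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for genome-wide serpin (serine protease
    inhibitor) gene-family analysis in hexaploid wheat and similar polyploids.
    Implements structural curation of candidate serpins (length gate,
    scaffold-conservation check against a reference serpin, reactive-centre-loop
    localisation with P-site nomenclature, hinge validation and inhibitory
    classification), gene-model quality control and pseudogene detection
    (splice sites, frameshifts, premature stops), codon-level variant
    consequences and isoelectric points, homeologue-triad construction with
    A:B:D pattern classification, tandem-duplication detection, Nei-Gojobori
    Ka/Ks with Jukes-Cantor correction, neighbour-joining phylogeny with
    bootstrap support and clade partitioning, and TPM-threshold expression
    profiling (tissue specificity and stress response).  A synthetic hexaploid
    gene-family generator with machine-readable planted ground truth exercises
    every stage end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
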