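Package: ytriage
Title: Triage and Annotation of Flow-Sorted Y Chromosome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing contig assemblies of flow-sorted mammalian Y
    chromosomes. Classifies contigs into male-specific (MSY), pseudoautosomal
    (PAR) and contaminant fractions by identity/coverage homology gates against
    a female reference, profiles per-contig sequence features (GC, interspersed
    and simple repeats, N50/L50 metrics), detects multicopy gene architecture
    with orientation and truncation status from spliced transcript-to-contig
    alignment, locates the pseudoautosomal boundary by windowed homology
    changepoint detection, estimates relative gene copy number from qPCR cycle
    thresholds by the 2^-ddCt method, and builds neighbor-joining trees from
    p-distances. Includes a deterministic synthetic-study generator that plants
    a known PAR/MSY architecture for validation, a seed-and-extend local
    alignment engine, and readers/writers for FASTA, GFF3, BED, TSV and Newick.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    phangorn,
    purrr,
    Rcpp,
    readr,
    rlang,
    stringr,
    tibble,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
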