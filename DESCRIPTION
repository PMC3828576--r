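Package: idrscape
Title: Chromosomal Landscapes of Intrinsic Protein Disorder, Recombination and G+C Content
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how intrinsically disordered protein segments
    are distributed along plant chromosomes and how that distribution relates
    to genetic recombination rates and coding-sequence G+C content. Extracts
    maximal disordered segments (length >= 30 residues) from per-residue
    disorder predictions, classifies disordered residues relative to annotated
    structural domains (in-domain, linker, N- and C-terminal), scores
    conservation of disordered-segment counts across paralogue pairs
    stratified by chromosomal location, partitions gene G+C content into
    disordered and ordered fractions, aggregates all of these into genome
    windows matched to empirical genetic-map intervals (cM/Mb), and fits the
    associated statistics: Pearson correlations with significance bands,
    variance-to-mean dispersion indices, multiple regression with sequential
    ANOVA and diagnostics, and hypergeometric annotation-term enrichment. A
    fully parameterised synthetic-genome simulator with known ground truth
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    lmtest,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
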