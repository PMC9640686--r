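Package: streptopan
Title: Bacterial Pangenome Construction and Functional Conservation Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for desk-scale bacterial pangenomics modelled on comparative
    analyses of the genus Streptomyces. Builds orthologous groups from
    all-vs-all protein similarity (Smith-Waterman local alignment, 80 percent
    identity and 70 percent dual coverage thresholds) as connected components
    of the qualifying-hit graph; computes gene accumulation and core-genome
    curves, conservation-bin histograms and per-genome profiles; joins
    orthologous groups with functional annotation tables (COG, KEGG, CAZyme,
    biosynthetic gene cluster types) into conservation profiles; classifies
    sigma factors, transcription factors, chaplins and phosphopantetheinyl
    transferases from Pfam domain architectures; scores beta-ketoadipate
    pathway completeness per genome; and clusters strains from CAZyme
    presence-absence matrices. Includes a synthetic pangenome generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
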