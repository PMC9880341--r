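Package: slinfer
Title: Synthetic Lethal Interaction Inference from Multi-Omics and Yeast
    Genetic Screens
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Local, file-based inference of candidate synthetic lethal
    gene pairs in cancer. Implements three complementary workflows:
    DAISY-style screening (genomic survival of the fittest, functional
    examination, and pairwise co-expression, intersected), mutation-
    dependent synthetic lethality prediction (MDSLP; mutation-stratified
    differential gene-dependency testing with FDR control), and the
    conserved genetic interaction (CGI) workflow mapping negative yeast
    SGA interactions to human pairs through an ortholog map. Includes
    exactly-verifiable statistical kernels, binary molecular-state
    calling from expression, copy number and mutation data,
    hypergeometric gene-set enrichment, a seeded synthetic-cohort
    generator with planted ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
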