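Package: crisprgates
Title: Design and Simulation of dCas9 sgRNA-Repressible Promoter Logic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for engineering transcriptional logic in bacteria from
    catalytically dead Cas9 (dCas9) and single guide RNAs. Generates
    orthogonal 13-bp operators embedded in the 17-bp spacer of synthetic
    sigma-70 promoters, derives template- and non-template-targeting 20-nt
    guides, screens their 12-nt PAM-adjacent seeds against a genome for
    off-target sites, plans annealed-oligo and Golden Gate construction of
    sgRNA transcription units, fits power-law gate response functions and
    Hill inducer curves, and compiles NOT/NOR netlists into steady-state,
    truth-table and dynamic predictions, including knockdown guides against
    endogenous coding sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
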