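Package: vlcfa
Title: Very Long-Chain Fatty Acid Elongation Analysis from GC-MS Yeast Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the functional characterization of Elovl4 fatty-acid
    elongases from heterologous yeast expression assays. Implements
    fatty-acid shorthand nomenclature and FAME monoisotopic mass / SIM
    channel computation, the stepwise elongation-conversion statistic
    applied to GC-MS peak areas, very long-chain saturated fatty-acid
    profile comparison (Levene, one-way ANOVA, Tukey HSD compact letter
    display), a typed LC-/VLC-PUFA biosynthesis pathway graph with route
    enumeration (Sprecher vs Delta-4), diagnostic Elovl motif scanning,
    pairwise global protein identity, in-silico PCR, qPCR absolute
    quantification via standard curves with beta-actin normalization, and a
    seeded synthetic-data generator emulating the yeast assay design so
    every pipeline stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    car,
    igraph,
    Biostrings,
    readr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
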