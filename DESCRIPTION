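Package: optfam
Title: Evolutionary Expansion Analysis of the Rice Oligopeptide Transporter Gene Family
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for gene-family evolutionary-expansion
    analysis, built around the sixteen rice oligopeptide transporter (OsOPT)
    genes. Screens candidate proteins for family membership by signature
    motif and physicochemical parameters; builds neighbor-joining trees from
    Poisson-corrected amino-acid distances with bootstrap support and
    clade-based subfamily assignment; estimates Ka, Ks and Ka/Ks for
    duplicated gene pairs by Nei-Gojobori (1986) pathway counting with
    Jukes-Cantor correction and classifies the selection regime; classifies
    duplicate pairs as tandem or segmental from gene position tables and
    collinear blocks; dates duplication events by the molecular clock
    T = Ks/(2*lambda) and assigns evolutionary stages; and scores expression
    diversification of duplicated pairs from tags-per-million digital
    expression data under a two-fold response rule. Includes seeded
    simulators for codon-pair divergence, chromosome gene maps with planted
    duplications, and tag-count matrices, so every stage is testable with
    controlled ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
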