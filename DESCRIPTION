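Package: mirkey
Title: Key microRNA Discovery from Paired Tumor/Normal Expression Profiles
Version: 0.1.0
Authors@R: person("mirkey", "developers", role = c("aut", "cre"),
    email = "mirkey@example.org")
Description: A reproducible pipeline for nominating key regulatory
    microRNAs from paired tumor/adjacent-normal expression profiles.
    Covers fold-change based differential-expression calling across
    tumor grades, intersection to a commonly dysregulated set, canonical
    seed-match target prediction (6mer, 7mer-A1, 7mer-m8, 8mer sites in
    3'UTRs), hypergeometric GO/KEGG gene-set enrichment with
    Benjamini-Hochberg FDR control, cancer-pathway screening, and
    bipartite miRNA-gene network construction with degree-based key-miRNA
    ranking.  Includes validation-assay arithmetic (delta-delta-Ct
    relative quantification, dual-luciferase normalization, two-sample
    t-tests) and a synthetic-data generator that plants known fold
    changes, seed sites and enriched terms so every stage is testable
    end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
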