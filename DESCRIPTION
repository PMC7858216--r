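Package: superbarcode
Title: Design and Evaluation of Chloroplast DNA Barcodes for Species
    Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing organellar DNA barcodes and identifying
    specimens from them. Scans aligned chloroplast genomes for hypervariable
    regions with a sliding-window nucleotide diversity statistic, selects and
    merges candidate barcode regions, evaluates the species-discrimination
    power of any marker by bootstrap-supported monophyly on maximum-parsimony
    or neighbor-joining trees, and assigns query samples (e.g. seed-bank
    accessions) to species by clade membership, flagging mislabeled
    accessions. Includes a synthetic-data generator that emulates a
    rice-like (Oryza) species complex with clade structure, localized
    rate heterogeneity and planted mislabels, so the whole pipeline can be
    exercised without external sequence downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
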