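Package: emsmapr
Title: Bulked-Segregant Mapping and Sector Phasing of EMS-Induced Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps ethyl methanesulfonate (EMS) induced recessive mutations
    from pooled whole-genome variant calls by bulked segregant analysis
    (homozygosity filtering, mutation-spectrum filtering, per-megabase
    variant-density binning and interval detection), classifies candidate
    single-nucleotide variants by codon-level consequence within gene models,
    and identifies and phases novel noncomplementing alleles from paired
    sterile/fertile chimeric-sector sequencing using read-backed cis/trans
    phasing. Includes a synthetic EMS-screen generator (F2 segregation with
    Haldane linkage, binomial read sampling, sequencing error, planted
    background and error-prone sites) so every pipeline stage can be
    exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
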