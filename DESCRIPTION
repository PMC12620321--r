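Package: rflpkit
Title: In Silico PCR-RFLP Assay Design and Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and interpreting PCR-RFLP (cleaved amplified
    polymorphic sequence) assays entirely in silico: virtual PCR with IUPAC
    degenerate primer matching, restriction-site scanning and digestion of
    haploid and heterozygous templates including offset (type IIS-like)
    cutters, virtual agarose gel electrophoresis with densitometric peak
    quantification, discovery of diagnostic enzymes over haplotype alignments
    with minimal panel selection, and a genotype caller for haplotype and
    hybrid identification from observed band patterns. Ships a synthetic
    internal transcribed spacer (ITS) haplotype fixture modelled on a licorice
    (Glycyrrhiza) species-identification assay, plus simulators for SNP-bearing
    haplotypes, diploid populations, Sanger-style site calls and noisy gel
    lanes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    zoo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
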