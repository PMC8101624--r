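Package: enhpro
Title: Epigenomic Prioritization of Regulatory GWAS Variants in a Focal Cell Type
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate causal regulatory variants from GWAS
    association tables by combining linkage-disequilibrium proxy expansion
    (with an EM haplotype-frequency estimator), cell-type-preferential
    enhancer/promoter chromatin-state filtering against 18-state genome
    segmentations and H3K27ac/DNaseI narrowPeak tracks, gene prioritization
    by preferential RPKM expression, and allele-specific transcription-factor
    binding-site prediction from TRANSFAC-style position weight matrices.
    Includes a seeded synthetic-data generator with planted causal and decoy
    variants so every stage of the pipeline can be validated end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
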