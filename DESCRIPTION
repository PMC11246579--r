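Package: capcore
Title: Targeted-Remapping Genotyping Toolkit for Target Enrichment Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational stages for genotyping target enrichment capture
    experiments on large genomes: coverage-driven sub-reference construction
    (zone calling, interval merging, sub-reference FASTA extraction),
    pair-aware zone-by-zone read extraction with single-end demotion,
    variant coordinate lift-over from sub-reference contigs back to full
    chromosomes, a four-stage VCF filtering cascade with population-genetic
    criteria (genotype DP/GQ masking, locus QUAL/missingness filters,
    sample filters, FIS and minor-allele-homozygote rules), and the QC and
    diversity statistics used downstream (Ts/Tv, nucleotide diversity,
    diversity reduction index, Weir & Cockerham Fst and per-zone Fst scans).
    Includes a synthetic-fixture simulator with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
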