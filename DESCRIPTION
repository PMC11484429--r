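Package: mhcasm
Title: Haplotype-Guided De Novo Assembly of the MHC Region from Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-informed, haplotype-guided de novo assembly of the
    hyperpolymorphic major histocompatibility complex (MHC) from paired-end
    Illumina reads. Individuals are assigned one or two guide haplotypes from
    their HLA-DRB1 first-field genotype, reads are binned by alignment to each
    guide, mapped reads are grouped into superblocks and assembled with a de
    Bruijn graph assembler (k = 51 by default), contigs are filtered, merged,
    polished and scaffolded against the guide under a placement-score filter,
    and a single continuous consensus haplotype is emitted together with
    unplaced contigs. Includes a synthetic diploid region and read simulator,
    read quality control (poly-G removal, seeded subsampling, quality
    trimming), and a validation toolkit (assembly statistics, truth-based
    error taxonomy, novel-variant recovery, kmer diversity, PAF export).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
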