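Package: aseScan
Title: Allele-Specific Expression and Selective-Sweep Scanning in F1 Hybrids
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects allele-specific expression (ASE) at breed-discriminating
    SNPs in F1 hybrids of two divergent parental populations, scans the
    parental genomes for selective sweeps with windowed Weir-Cockerham Fst and
    pooled heterozygosity (Hp) Z-scores, and intersects both result sets into
    "core-ASE" genes: genes with cis-regulatory imbalance that also lie in
    regions of directional selection. Ships a truth-labelled synthetic-data
    generator (parental and F1 VCF, RNA alignments or allele-count tables,
    GFF3 gene models, imprinted-gene list, FPKM table) so the whole pipeline
    can be exercised and validated end to end without access to real data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
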