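Package: transmark
Title: Transcriptome-Derived SNP, CAPS and SSR Marker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-assembly molecular marker discovery for non-model plant
    transcriptomes. Implements a two-round hard-filtering pipeline for
    multi-sample transcriptome SNP calls (cluster, mapping-quality,
    strand-bias, allele-frequency, quality, depth, transcript-edge and
    exon-boundary filters), per-site classification (UTR/CDS region,
    transition/transversion class, zygosity, pairwise polymorphism,
    minor-allele read-count frequency, IUPAC masking), summary statistics
    (SNP frequency, Ts/Tv tables, per-unigene distributions, Venn
    partitions, assembly N50), cleaved amplified polymorphic sequence
    (CAPS) marker prediction by differential restriction digestion with
    fragment-ladder prediction and amplicon/primer design, MISA-style
    microsatellite (SSR) detection with motif canonicalization and
    constrained primer design, and a deterministic synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    vcfR,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
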