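Package: uorfscan
Title: Discovery of Upstream Open Reading Frames and Annotation of
    uORF-Disrupting Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide discovery of upstream open reading frames (uORFs)
    in transcript leader sequences from a reference genome and UCSC
    refGene-style transcript models, with splice-aware projection of uAUG
    and uStop codons to genomic coordinates and Kozak-context
    classification.  Includes the candidate-mutation filter used for
    multiplex amplicon deep-sequencing screens (coverage and
    allele-deviation thresholds, multi-allelic noise exclusion, known-SNP
    partition), multi-caller somatic consensus filtering of VCFs subset to
    uORF elements, classification of start-loss, stop-loss and
    Kozak-altering single nucleotide variants, and a seeded synthetic-data
    generator that produces genomes, transcript tables, caller VCFs and
    per-site base counts with a ground-truth manifest for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
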