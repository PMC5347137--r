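Package: nmdpipe
Title: Nonsense-Mediated Decay Target Annotation and Longevity Assay Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates transcripts for features that mark them as putative
    targets of nonsense-mediated mRNA decay (NMD): premature termination
    codons by the 50-nt exon-junction rule, upstream open reading frames in
    the 5' UTR, and 3' UTR length categories. Provides the downstream
    statistics used in insulin/IGF-1-signalling longevity transcriptomics:
    genotype-contrast enrichment (chi-squared fraction tests, rank-sum tests
    by 3' UTR class), restoration analysis across a four-genotype design,
    hypergeometric gene-set overrepresentation with the EASE variant, mRNA
    half-life estimation from transcription-shutoff time courses, comparative
    Ct quantification, and Kaplan-Meier/log-rank lifespan analysis. A
    synthetic-data module generates genomes, annotations, expression tables,
    decay curves and survival tables with planted ground truth so the whole
    pipeline is testable offline.
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
    survival,
    Biostrings,
    rtracklayer,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
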