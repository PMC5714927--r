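Package: msapseq
Title: Simulation and Analysis of Methylation-Sensitive Amplification
    Polymorphism Sequencing (MSAP-Seq) Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for methylation-sensitive restriction enzyme sequencing
    (MSAP-Seq) of CCGG sites. Provides an in-silico simulator of the wet-lab
    protocol (EcoRI + HpaII double digestion with methylation-aware blocking,
    adapter ligation, selective-primer amplification, sonication and read
    synthesis) together with the complete downstream pipeline: HpaII-adapter
    tag filtering, assignment of tags to genomic CCGG sites, reads-per-million
    normalization, four-category genomic feature annotation with GO
    enrichment, differential-methylation calling (exact conditional rate
    test with Benjamini-Hochberg correction for replicated designs, a
    fold-change rule for unreplicated designs), reversibility classification,
    hierarchical clustering QC and MSRE-qPCR validation arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
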