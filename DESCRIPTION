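Package: regenmeth
Title: Differential DNA Methylation Analysis of Liver Aging and Regeneration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for whole-genome bisulfite sequencing (WGBS) differential
    methylation analysis across paired condition contrasts, modelled on the
    mouse liver aging-by-regeneration design. Calls differentially methylated
    cytosines (DMCs) from replicate CpG count tables by pooled Fisher exact or
    credible-difference statistics, assembles differentially methylated
    regions (DMRs) by a sliding-window rule (three or more consecutive
    same-direction DMCs within 300 bp), classifies DMRs across contrasts into
    temporal categories (early single, late single, progressive, inverse) and
    cross-condition synchronous/inverse pairs, computes three-set Venn
    accounting over overlap-connected components, annotates DMRs against a
    genomic hotspot vocabulary (gene structures, repeats, CpG islands), links
    DMRs to differentially expressed genes through strand-aware promoter
    windows with direction matching, and simulates seeded synthetic methylomes
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
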