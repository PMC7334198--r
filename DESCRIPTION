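Package: pextr
Title: Transcript Expression-Aware Variant Annotation (pext)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the proportion expressed across transcripts (pext) for
    variant annotations: the fraction of a gene's total transcriptional output
    carried by the transcripts on which a variant has a given consequence,
    per tissue and averaged across tissues. Reads isoform quantifications
    (RSEM, salmon, or generic TPM matrices), aggregates median transcript
    expression per tissue, combines it with per-transcript variant
    consequences (VEP-style CSQ annotations or a built-in minimal classifier
    against GTF gene models), and derives ext/pext values, base-level
    expression tracks, expression bins, and a gene-level quality filter.
    Includes the downstream validation statistics used with this annotation:
    mutability-adjusted proportion singleton (MAPS), exact Poisson rate
    ratios for de novo burden comparisons, Fisher tests for filtering
    comparisons, and a conservation-versus-expression logistic regression.
    A synthetic-data generator produces gene models, expression matrices and
    variant sets with analytically known pext for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    optparse,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
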