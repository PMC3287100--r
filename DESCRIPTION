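Package: codonbias
Title: Synonymous Codon Usage Bias Analysis for Viral Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying synonymous codon usage bias in sets of
    protein-coding sequences: codon counting, nucleotide composition at all
    and at synonymous third codon positions, relative synonymous codon usage
    (RSCU), Wright's effective number of codons (ENC) with its expected
    GC3-driven curve, principal component analysis of strain-by-codon RSCU
    matrices, Pearson correlation suites over composition variables, and
    comparison of a viral codon usage profile against a bundled human
    reference. Includes a synthetic coding-sequence cohort generator with
    independently controllable mutational composition and within-family
    codon selection, so that every stage of the pipeline can be exercised
    and calibrated without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
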