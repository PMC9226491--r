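Package: cubtools
Title: Codon Usage Bias Analysis for Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing codon usage bias in sets of protein-coding
    sequences: FASTA admission and validation, nucleotide composition by codon
    position, dinucleotide odds ratios, relative synonymous codon usage (RSCU)
    with representation calls, rare-codon screening, the codon adaptation
    index (CAI), Wright's effective number of codons (ENc), the intrinsic
    codon bias index (ICDI), evolutionary-force diagnostics (PR2 parity,
    GC12-GC3 neutrality regression, the expected ENc-GC3 curve, composition
    regressions and correlations, PCA on RSCU vectors), protein
    physicochemical indices, a seeded synthetic-CDS generator with controlled
    bias, GC structure and dinucleotide depletion, and a one-call report
    pipeline that writes the full analysis surface as plain-text tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
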