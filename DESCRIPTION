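Package: mitocode
Title: Comparative Mitogenomics and Mitochondrial Genetic-Code Variant Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated insect mitochondrial
    genomes: strand-aware gene extraction from GenBank flat files or FASTA plus
    feature tables; AT/GC skew, codon-position G+C and GARP amino-acid
    composition statistics; alignment-based inference of codon reassignments
    (e.g. AGG Ser versus Lys) from conserved alignment columns; tRNA anticodon
    extraction and wobble decoding with tests of association between anticodon
    state and inferred codon meaning; non-coding region census, control-region
    tandem-repeat annotation and repeat-masked identity; and a synthetic
    mitogenome simulator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
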