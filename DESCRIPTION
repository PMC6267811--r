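Package: benchrep
Title: Representativeness Assessment of Variant Benchmark Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how representative a benchmark dataset of single
    amino acid substitutions is of the human protein universe. Variants are
    resolved through identifier cross-references to canonical proteins and
    through SIFTS-style residue maps to observed structure residues, then
    projected into chromosome, CATH, Pfam, Enzyme Commission and Gene
    Ontology category spaces. Bias is tested with weighted two-tailed
    binomial and chi-square tests on chromosomal counts and two-sample
    Kolmogorov-Smirnov tests on category frequency vectors; coverage of
    each classification scheme and contamination by common (high minor
    allele frequency) variants are reported alongside a per-dataset
    summary score. A synthetic proteome generator with controllable
    study-bias emulates every reference input so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
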