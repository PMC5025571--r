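Package: countnorm
Title: Scaling Normalization of RNA-Seq Count Matrices (TMM, RLE, MRN)
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the three scaling normalization methods for RNA-seq
    count matrices -- the trimmed mean of M-values (TMM), relative log
    expression / median-of-ratios (RLE), and median ratio normalization
    (MRN) -- as a single step-by-step decomposition: pre-normalization by
    library size, reference selection, relative scaling factors, unit-product
    adjustment, effective library sizes, size factors, and normalized counts
    (counts-per-million for TMM). Provides executable numeric verifiers for
    the equivalence propositions that link the three methods in simple
    designs (no replicates; two conditions), a negative-binomial synthetic
    count generator with controllable composition bias for testing, TSV/CSV
    readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
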