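Package: clonemix
Title: Subclone Inference from Single-Cell SNV Genotype Matrices via a
    Binary Mixture Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clusters tumor single cells into subclones from noisy binary
    single-nucleotide-variant genotype matrices using a probability mixture
    model for binary data fitted by expectation-maximization. False-positive
    and false-negative (allele dropout) rates are estimated jointly with the
    subclone genotypes; the number of subclones is selected with an
    inter-cluster-variance score. Includes a clonal-tree simulator with
    doublet and missing-data injection, clustering and genotyping accuracy
    metrics, and a minimum-spanning-tree lineage builder over inferred
    subclone genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    ape,
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
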