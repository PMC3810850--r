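Package: ptpdelim
Title: Species Delimitation on Phylogenies with Poisson Tree Processes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maximum-likelihood species delimitation on rooted phylogenies
    under the Poisson tree processes (PTP) model, in which among-species
    speciation events and within-species branching events each follow an
    independent Poisson process over the number of substitutions, so branch
    lengths in each class are exponentially distributed.  Provides exact
    enumeration and counting of candidate delimitations, exhaustive and
    hill-climbing likelihood searches, a likelihood-ratio test against a
    single-rate null model, a fixed-speciation-rate mode for reference-guided
    delimitation, a Yule / multispecies-coalescent simulator producing gene
    trees with known species partitions, and normalized mutual information
    for comparing delimitations with a ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
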