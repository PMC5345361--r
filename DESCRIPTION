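Package: barcodegap
Title: DNA Barcoding Species Delimitation and Barcode Gap Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for DNA-barcoding species delimitation in aligned
    mitochondrial or endosymbiont gene fragments. Computes pairwise genetic
    distances (p, JC69, K2P) with pairwise deletion, the five classical
    inter/intra-specific divergence statistics, barcode-gap overlap analysis,
    and putative-species partitions by four methods: single-linkage threshold
    clustering on neighbor-joining distances, Automatic Barcode Gap Discovery
    (ABGD), the single-threshold General Mixed Yule Coalescent model (GMYC),
    and the Poisson Tree Processes model (PTP). Estimated partitions are
    scored against reference (morphological) species as accurate, split,
    lumped, or partial-lumped clusters. A multispecies-coalescent simulator
    with K2P sequence evolution generates calibrated benchmark data sets so
    the whole pipeline can be exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
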