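Package: gitscore
Title: Genetic-Interaction-Network-Assisted Target Identification for
    Chemical Genomic Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scores candidate drug targets in haploinsufficiency (HIP) and
    homozygous (HOP) chemical-genomic fitness screens by propagating
    fitness-defect (FD) scores over a signed, weighted genetic-interaction
    network.  Implements the GIT family of scores (one-hop for HIP, two-hop
    for HOP, general k-order), the FD-score and the correlation-based
    rho-score baselines, z-score combination of HIP and HOP assays, top-k
    recovery evaluation with normalized AUC, a signed-degree-preserving
    network randomization test, and k-means clustering of score profiles
    with Fisher's exact gene-set enrichment.  Includes a synthetic screen
    generator with planted compound-target structure so the whole pipeline
    can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
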