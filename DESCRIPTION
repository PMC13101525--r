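Package: phycoassembly
Title: Community Assembly Analysis for Host-Associated Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for dissecting how host-associated (e.g. phycosphere)
    microbial communities assemble: Sloan neutral community model fitting
    with bootstrap confidence intervals and neutral-envelope taxon
    classification, Spearman co-occurrence networks with robustness and
    vulnerability stability metrics, alpha/beta diversity and principal
    coordinates analysis, permutation statistics (ANOSIM, PERMANOVA,
    Mantel) implemented from their definitions, core/accessory/specific
    taxon partitioning with UpSet-style intersection counts, and a
    taxonomy-function decoupling analysis. Includes a seeded synthetic
    community generator (Moran-type neutral assembly from a shared
    metacommunity plus guild-based functional redundancy) so every stage
    is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    igraph,
    picante
Config/testthat/edition: 3
RoxygenNote: 7.3.3
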