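Package: orscreen
Title: Receptor-Optimized Molecular Descriptor Screening for Odorant
    Receptor Ligands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand-based virtual screening for odorant receptors from
    electrophysiological training panels. Classifies each receptor's active
    odorants by dendrogram branch selection on spike-rate distances, greedily
    selects a receptor-optimized molecular descriptor multiset by sequential
    forward selection against an activity-distance correlation objective,
    evaluates enrichment with accumulative-percentage-of-actives curves and
    cross-validated ROC analysis, ranks large compound libraries by distance
    to the nearest known active, derives breadth-of-tuning distributions,
    clusters receptors in descriptor, activity and predicted-ligand space, and
    exports receptor-ligand interaction networks. Includes a synthetic panel
    generator with planted descriptor structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    igraph,
    jsonlite
Suggests:
    ChemmineR,
    ChemmineOB,
    pROC,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
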