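Package: petals
Title: Petal Subnetwork Mining and Bimodal Coexpression Ranking for
    Mutated Driver Genes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mines "petal" subnetworks that connect a mutated cancer
    driver gene to candidate partner genes through a refined
    protein-protein interaction network, then ranks the petals against
    proteomic target lists using a bimodality statistic on
    activity-weighted coexpression with an empirical permutation null.
    Includes interaction-network reliability filtering (logistic
    regression over edge features), homology-based edge imputation from
    protein-family evidence, Gene Ontology association-rule path
    filtering, bounded simple-path enumeration, and a synthetic-data
    generator with planted ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
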