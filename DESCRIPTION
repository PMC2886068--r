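Package: biliphy
Title: Comparative Analysis of Bile-Salt Phenotypes Across Vertebrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative chemotaxonomy of bile salts (bile alcohols and
    bile acids). Parses systematic steroid nomenclature into structural
    descriptors, classifies compounds into the three broad types (C27 bile
    alcohols, C27 bile acids, C24 bile acids), assigns species bile-salt profile
    classes I-VI from compositional thresholds, flags unusual structural
    modifications, cross-tabulates profile complexity against diet, maps discrete
    bile-salt characters onto rooted phylogenies with parsimony ancestral-state
    reconstruction (Hartigan-generalized Fitch, polytomies supported), computes
    pairwise protein identity for enzyme comparisons, and annotates negative-mode
    mass-spectrometry peak lists with candidate bile-salt identities from
    monoisotopic [M-H]- masses. Includes a seeded synthetic-data generator
    (birth-death trees, Mk discrete characters, Dirichlet compositions) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
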