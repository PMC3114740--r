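Package: stratpars
Title: Weighted Parsimony, Branch Support and Stratigraphic Congruence for
    Combined Fossil and Molecular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combined-evidence parsimony analysis of matrices that mix
    morphological characters (scored for living and fossil taxa) with molecular
    characters (missing for fossils). Provides a Sankoff/Fitch scoring engine
    with unordered, ordered and irreversible characters, between-character
    scaling and implied weighting; heuristic and exhaustive tree search with
    backbone ("molecular scaffold") constraints under which fossil taxa float;
    Bremer and double-decay branch support including sequential crown-exclusion
    analyses; stratigraphic congruence statistics (ghost lineages, MIG, MSM*,
    GER) with permutation significance; Templeton and winning-sites tests for
    suboptimal topologies; most-parsimonious ancestral-state reconstruction
    (ACCTRAN, DELTRAN, full MPR enumeration) with homology-versus-analogy
    classification of shared states; and a birth-death simulator that generates
    matched trees, character matrices, fossil-style missingness and
    stratigraphic ages for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
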