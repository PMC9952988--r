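Package: protspace
Title: Clade-Specific Amino-Acid Substitution Models and Protein Model Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring the structure of evolutionary model space for
    proteins. Trains clade-specific 20-state general time-reversible (GTR)
    amino-acid substitution models jointly from collections of protein
    alignments, each with its own tree; computes Euclidean distances among
    normalized exchangeability vectors; clusters models into a neighbor-joining
    "tree of models" and tests its congruence with a reference phylogeny using
    the matching split distance against a random-tree null; classifies
    alignments by model fit with BIC; and analyzes which exchangeabilities and
    equilibrium frequencies drive model differences (GC-content regressions of
    amino-acid classes, acidic:basic ratios, ranked exchangeability
    differences). Includes a full synthetic-data generator (random topologies,
    controlled model perturbations, sequence simulation under GTR with
    discrete-gamma rates and invariant sites) so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
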