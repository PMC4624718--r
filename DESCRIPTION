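Package: ddgprof
Title: Binding Free-Energy Changes upon Mutation from Structural Interface Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the change in protein-protein binding free energy upon
    mutation (ddG, kcal/mol) from position-specific structural profiles of
    analogous binding interfaces. Parses dimeric complex structures, computes
    solvent accessibility and interface residue classes (core, rim, support,
    interior, surface), aligns binding interfaces with three similarity
    metrics (iTM-score, Iscore, PCscore), builds Henikoff-weighted
    BLOSUM-mixed interface profiles including an adaptive strict/loose-cutoff
    profile, derives profile-quality and sequence features, curates
    experimental mutation tables, and combines all features in a random-forest
    regression model evaluated by repeated k-fold and leave-one-protein-out
    cross-validation. Includes deterministic generators for synthetic dimers,
    template families and mutation tables so the full pipeline can be
    exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    bio3d,
    Biostrings,
    randomForest,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
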