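Package: promisc
Title: Sequence-Based Prediction of Substrate Promiscuity in Ester Hydrolases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts substrate promiscuity of ester hydrolases (EC 3.1) from
    primary sequence. Builds length-independent physicochemical descriptors from
    protein sequences and evolutionary descriptors from PSI-BLAST position
    specific scoring matrix (PSSM) profiles, selects compact weighted feature
    sets with filter, wrapper and embedded methods, trains an abstaining
    agreement ensemble of shallow classifiers (support vector machine, k-nearest
    neighbours and a ridge linear classifier) under a repeated stratified split
    protocol, gates predictions with a k-nearest-neighbour applicability domain,
    and runs a staged bioprospecting workflow of profile-HMM homology pre-filter,
    ensemble prediction, and binding-cavity descriptor ranking. Includes a
    synthetic-data module (random proteins, synthetic PSSM profiles,
    planted-signal labels, mock HMMER hit tables and cavity tables) so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    Biostrings,
    e1071,
    ranger,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
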