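Package: lieScreen
Title: Virtual Screening and Linear Interaction Energy Analysis for
    Acetylcholinesterase Inhibitor Discovery
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for a combined machine-learning and molecular-dynamics
    screening workflow against acetylcholinesterase: compound libraries with
    binary fingerprints and Tanimoto similarity search, regression of binding
    free energy from molecular descriptors with thermodynamic conversion of
    Ki/IC50 activities (dG = RT ln K), multi-round similarity-search
    enrichment campaigns with per-round distribution summaries, linear
    interaction energy (LIE) binding free energy estimation from bound and
    unbound interaction-energy traces with replica aggregation, geometric
    hydrogen-bond and side-chain contact analysis of receptor-ligand
    trajectories with Kabsch-fitted RMSD, and an experimental validation
    report for acetylcholinesterase inhibitor complexes. Synthetic generators
    for scaffold-clustered libraries, autocorrelated energy traces and
    trajectories with planted contacts make the full pipeline testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    xgboost,
    ranger
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
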