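Package: entangleAge
Title: Native Lasso Entanglements and Age-Associated Structural Change in Proteomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects native non-covalent lasso entanglements (NCLEs) in
    protein structures by discretized Gaussian linking integrals, classifies
    age-associated structural changes from limited-proteolysis mass
    spectrometry (LiP-MS) peptide tables, and quantifies their association at
    the protein and residue level with crude and length-adjusted odds ratios.
    Includes a C-alpha structure-based (Go-type) model with a Langevin
    temperature-quench refolding protocol, fraction-of-native-contacts (Q)
    and entanglement-change (G) trajectory metrics with KMeans++/PCCA+
    state clustering and misfolding-probability estimation, a Shrake-Rupley
    solvent-accessibility permutation test for LiP-MS consistency, and
    seed-deterministic synthetic-data generators with planted ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
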