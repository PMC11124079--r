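Package: nanofp
Title: Coordination-Environment Fingerprints and Toxicity QSAR for Metal Oxide Nanoparticles
Version: 0.1.0
Authors@R: person("nanofp", "developers", email = "nanofp@example.org", role = c("aut", "cre"))
Description: Builds fixed-layout count-vector descriptors ("NanoFingerprints") of
    the shell of a binary metal-oxide nanoparticle from its 3D structure in XYZ
    format: bonds are inferred from covalent radii, atoms are classified into
    core and shell by a radial thickness, and local coordination environments
    O(x,y)/M(x,y) and bonded pairs thereof are counted into a four-section
    vector. Also provides labelled subgraph search of small query structures in
    the shell, leave-one-out linear and cross-validated logistic toxicity QSAR
    protocols that concatenate fingerprints with physicochemical features, a
    log-scale regression that predicts whole fingerprints from particle size
    alone, synthetic lattice-cut particle and QSAR dataset generators, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet
Config/testthat/edition: 3
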