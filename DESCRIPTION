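Package: scmfold
Title: Primary-Contact Scanning and Folding-Interdiction Analysis under the Sequential Collapse Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans protein sequences for the early non-local hydrophobic
    contacts that nucleate folding under the sequential collapse model
    (SCM). Windowed Fauchere-Pliska hydrophobicity sums are combined with a
    loop-closure entropy penalty and a side-chain ordering cost to score
    candidate primary contacts, from which Boltzmann folding-channel
    populations, perturbation-based confidence shifts and merged kinetic
    channels are derived. A folding-interdiction stage maps exogenous
    peptides onto the contacts they can block and models the redistribution
    of folding flux among the surviving channels. Includes a synthetic
    sequence generator with planted hydrophobic segment pairs and an
    independent brute-force scoring oracle for verification, plus the core
    domain of human p53 (residues 94-297) as a built-in worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
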