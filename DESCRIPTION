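Package: pyrosite
Title: Prediction of Pyrrolidone Carboxylic Acid Modification Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Sequence-based prediction of internal pyrrolidone carboxylic
    acid (pyroglutamate) modification sites. Builds 21-residue peptide
    window datasets around candidate glutamine residues, encodes each
    window into a 727-dimensional feature vector (PSSM conservation
    scores, Atchley amino-acid factors, disorder, secondary structure,
    solvent accessibility, evolutionary gain/loss, interface/surface
    conservation propensity, and side-chain carbon-count deviation),
    ranks features by maximum-relevance minimum-redundancy mutual
    information, and evaluates nearest-neighbour classifiers under
    jackknife cross-validation with incremental feature selection.
    Includes a synthetic fixture generator so the whole pipeline is
    testable without external databases or prediction servers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
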