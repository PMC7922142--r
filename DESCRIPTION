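Package: pKaSpectra
Title: Atom-Typed Distance-Spectrum Prediction of Carbon Acid pKa
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts aqueous pKa values of carbon acids from a topological
    "distance spectrum": every heavy atom is assigned a six-digit ABBCDD
    atom-type code and contributes the inverse square of its through-bond
    distance to the ionisation site to the entry of its type. Atom-type
    coefficients are learned by a deterministic QR least-squares solve, and
    predictions report an applicability-domain flag (inDomain) that is true
    only when every atom-type in the query spectrum has a learned
    coefficient. The package also fits AIBL-style local linear models
    (pKa = m*R + c) on user-supplied bond lengths, applies mixed-solvent to
    water corrections, and emits virtual training records so sparse
    experimental sets can be augmented; curation utilities implement damped
    averaging of replicate pKa measurements and greedy smallest-error
    assignment of experimental values to candidate ionisation sites.
    Validation tools provide stratified RMSE, Y-scrambling, and absolute
    error and coefficient-magnitude binning. A synthetic fixture generator
    with known ground-truth coefficients makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
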