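Package: infoeff
Title: Semantic Information Measures and Maximum Information-Efficiency Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for semantic information theory over finite alphabets:
    discrete sources, Shannon channels, semantic channels (truth/membership
    tables) and likelihood families linked by the semantic Bayes formula;
    Shannon and semantic mutual information with full variational-free-energy
    diagnostics; the information rate-fidelity function R(G) solved by
    Minimum Information Difference (MID) alternating minimization;
    EM/EnM/En algorithms for one-dimensional Gaussian mixture models with
    per-iteration traces that expose non-monotone variational free energy
    while the information difference R - G decreases; goal-oriented
    constraint control (active inference against fuzzy goals); and
    statistical-physics identity checks connecting mutual information,
    Boltzmann distributions and thermodynamic entropy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
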