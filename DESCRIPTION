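Package: aquamap
Title: Presence-Only Mapping of Water Access Points on Gridded Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating per-cell numbers of drinking-water access
    points (boreholes, piped connections, springs, wells, rainwater
    harvesting, surface water) from presence-only point registries and
    gridded feature layers. Implements maximum-entropy (Gibbs) and
    multi-layer-perceptron presence/background classifiers, uniform and
    population-weighted background sampling, scaling of relative
    probabilities to absolute expected counts via household-survey access
    shares, threshold-based TPR/FPR evaluation contrasted with AUC,
    background-ratio sensitivity sweeps, and household-survey validation
    statistics. A synthetic-world generator with known ground truth makes
    the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
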