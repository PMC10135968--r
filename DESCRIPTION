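Package: gabamod
Title: Two-State Co-Agonist Analysis of GABA-A Receptor Modulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies allosteric modulation of GABA-A receptors recorded in
    Xenopus oocytes under the two-state (resting-active) cyclic co-agonist
    model. Converts voltage-clamp current amplitudes to open probabilities
    using full-block and full-activation anchors, estimates per-cell gating
    efficacy (c) and active-state stabilization energy (delta-G) for
    positive allosteric modulators and anesthetics, performs mutant-cycle
    additivity analysis with propagated confidence intervals across
    intersubunit-interface mutations, scores substituted-cysteine
    modification-protection assays, and generates synthetic per-oocyte data
    sets with realistic cell-to-cell variability for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
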