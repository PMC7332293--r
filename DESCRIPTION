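Package: apmscore
Title: Comparative Scoring of Multi-Bait AP-MS Interactomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores affinity-purification mass-spectrometry (AP-MS)
    experiments in which many tagged baits are purified in parallel and
    each bait's samples are compared against the pooled samples of all
    other baits (a bait-specific control group design). Implements
    background-proteome median-of-ratios normalization, per-bait
    enrichment statistics with a moderated-variance or Welch t-test,
    semi-quantitative spectral-index (SINQ) quantitation with a
    sample-exclusivity rescue path for preys detected with a single bait,
    contaminant exclusion, the four-criterion high-confidence candidate
    interacting protein (HCIP) filter, and network-level summaries:
    prey-sharing distribution, abundance correlation, secretory-pathway
    classification, prior-knowledge overlap and a clustered p-value heat
    map. Includes a synthetic multi-bait AP-MS generator with ground
    truth so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
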