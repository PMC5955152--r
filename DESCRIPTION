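Package: synercurve
Title: Drug-Combination Synergy Scoring by Normalized AUSC Decrease and
    Combination-Unique Differential-Expression Set Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies drug-combination synergy across cell-line panels by
    the relative decrease in the trapezoidal area under the normalized
    survival curve (AUSC) between single-agent and combination dose-response
    curves, with per-curve anchor normalization that isolates curve shape
    from the pretreatment drug's own toxicity. Also filters bulk RNA-seq
    differential-expression tables (FDR, FPKM and fold-change thresholds,
    including infinite fold changes) and performs the set algebra that
    defines genes unique to a drug combination, with Venn region counts and
    time-point persistence summaries. Includes seeded simulators for
    Hill-model viability plates with planted synergy and for three-condition
    differential-expression tables with planted shared and combination-unique
    effects, so the whole pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
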