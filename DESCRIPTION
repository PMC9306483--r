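Package: sedscreen
Title: Risk-Based Screening of Organic Chemical Contaminants in Sediment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screening-level prioritization of organic chemicals and sampling
    sites from site-by-chemical sediment concentration data. Estimates dissolved
    porewater concentrations by equilibrium partitioning, computes sediment and
    porewater toxicity quotients against compiled quality benchmarks,
    exposure-activity ratios against high-throughput (ToxCast-style) bioactivity
    cutoffs, and additive mixture scores for PAHs (TEC/PEC quotients and
    equilibrium-partitioning sediment benchmark toxic units), alkylphenols
    (nonylphenol toxic equivalents), and shared assay endpoints. Aggregates the
    lines of evidence into chemical priority levels and multi-method site
    priority scores, joins assay endpoints to gene targets and adverse outcome
    pathways, and correlates screening metrics with watershed attributes. A
    seeded synthetic-study generator produces complete input tables with
    realistic censoring, partitioning, and contamination-gradient structure for
    testing and method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
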