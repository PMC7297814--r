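Package: srnaflow
Title: Differential Expression and Regulatory Analysis of Blood Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of small non-coding RNA sequencing of
    peripheral blood across an acute phase, a chronic phase and a control
    group: counts-per-million detectability filtering, negative-binomial
    quasi-likelihood differential expression with timepoint and direction
    pattern classification, closed-form and spike-in statistical power
    estimation, sRNA class-composition chi-square tests against randomly
    sampled nonregulated backgrounds, per-locus conservation-score averaging,
    and ChIP-seq transcription-factor binding-site overrepresentation against
    expression-matched backgrounds. Includes a negative-binomial synthetic
    study generator with planted ground truth so every stage is testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    edgeR,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
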