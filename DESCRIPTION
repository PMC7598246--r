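Package: sigrev
Title: Transcriptomic Signature Reversal for Drug Repurposing in Drug-Resistant Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a transcriptomics-based drug-repurposing
    workflow for drug-resistant cancer. Derives drug-resistance gene signatures from
    two-group expression or count data (noise filtering, probe collapsing, an
    empirical-Bayes moderated t-statistic, mean-false-positive control and fold-change
    cutoffs); scores drugs for signature reversal against a library of ranked
    perturbation profiles with the weighted Kolmogorov-Smirnov connectivity statistic;
    classifies patient samples as signature-positive or -negative by nearest-template
    prediction with resampling significance; stratifies survival (Kaplan-Meier,
    log-rank, hazard ratio); analyzes drug-target protein interaction networks
    (degree, clustering, eigencentrality, communities, edge enrichment); and applies
    a reproducible drug-prioritization ledger with a treatment-reversal concordance
    analysis. A synthetic-data module generates every input the pipeline consumes,
    with planted ground truth for recovery tests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    edgeR,
    igraph,
    survival
Suggests:
    limma,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
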