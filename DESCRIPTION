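Package: clocknet
Title: Differential miRNA Co-Expression Networks and Clock-Gene Target Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds condition-specific Pearson correlation networks from matched
    tumor/control miRNA expression profiles, compares them by coherence-based
    edge-set partitioning (common, condition-exclusive and sign-flip pairs),
    overlays validated miRNA to circadian clock gene target annotation, computes
    seven per-node topology indices under per-component normalization, and ranks
    candidate clock-targeting miRNAs by combining differential expression with
    topological rewiring evidence. Includes paired differential expression with
    signed fold changes and false discovery rate control, small validation
    statistics (gene-miRNA inverse correlation, 2^-ddCt relative quantification,
    median-split chi-squared association, microsatellite instability calls), and
    a seeded synthetic matched-cohort generator with planted correlation modules
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
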