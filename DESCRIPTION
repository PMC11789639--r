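Package: xybuffer
Title: Dosage Sensitivity and Expression Buffering of X-Y Gene Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies dosage sensitivity of homologous X-Y gene pairs and
    detects post-transcriptional auto- and cross-regulation between the
    homologs. Implements phylogenetic survival fractions of Y-linked genes
    from species trees and presence/absence data, constraint percentile
    ranks and tissue expression breadth with Pythagorean combination,
    dosage-response regression of transcript levels on sex-chromosome copy
    number, allelic-ratio analysis of Xi versus Xa expression, knockdown
    compensation and delta-delta-Ct qPCR analyses, and mRNA half-life
    estimation from metabolic-labeling time courses. A synthetic-data
    generator with known ground truth makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
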