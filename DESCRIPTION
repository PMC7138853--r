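Package: tmtpipe
Title: Multi-Plex TMT Proteomics Quantification and Downstream Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantification of multi-plex tandem-mass-tag (TMT) proteomics
    experiments from peptide-spectrum-match (PSM) tables, and the downstream
    inference that typically follows: PSM quality filtering, log2
    ratio-to-reference conversion, interquartile-range outlier removal,
    median roll-up to proteins, median/MAD ratio normalization,
    reference-intensity back-conversion to absolute abundances, integration
    of plexes, multiple imputation of missing abundances by chained
    equations with predictive mean matching and Rubin's-rules pooling,
    batch correction, differential expression, preranked gene set
    enrichment analysis, hierarchical clustering and PCA, and cross-species
    signature intersection with homolog mapping. Includes a synthetic
    PSM-level cohort generator with known ground truth so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    withr
Config/testthat/edition: 3
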