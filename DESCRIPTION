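Package: clonofocus
Title: T Cell Receptor Repertoire Clonality, Clonotype Tracking and Immune
    Gene Signature Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of bulk T cell receptor beta-chain (TCRbeta)
    repertoires from paired tissue and blood samples: reading and curating
    AIRR or immunoSEQ-style rearrangement exports into per-sample CDR3
    clonotype tables, Shannon-entropy clonality indices with an exact
    paired signed-rank comparison across compartments, top-N clonotype
    extraction and multi-sample overlaps, two-proportion chi-squared
    tracking of clonotype frequency changes with up/down/no-change calls,
    public/private classification against a local reference and
    edit-distance matching of CDR3s to virus-specific clonotypes with
    annotated substitutions, insertions and deletions, and a companion
    immune gene expression stage (log2 transform, PCA with Ward
    clustering, marker selection, median-based modified z-scores,
    signature correlation). A synthetic-data module generates
    repertoires, reference databases and expression matrices with
    ground-truth labels so every stage is testable without external
    downloads.
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
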