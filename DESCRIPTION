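Package: proxiome
Title: Proximity-Labelling Enrichment, Ribosome Occupancy and Sequence
    Feature Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis of TurboID/BioID proximity-labelling
    screens from protein-group iBAQ intensity tables: per-run median
    normalization, left-censored (downshifted Gaussian) imputation of
    control runs, and control-referenced log2 enrichment scoring under
    paired-control, pooled-median and replicate-averaged reference
    schemes. Also computes the polysome-anchored occupancy statistic for
    sucrose-gradient fraction profiles (normalized ribosomal-protein
    ratios with fraction-group summaries), sequence-level features
    (Henderson-Hasselbalch net charge and isoelectric point, average
    molecular mass, classical-NLS and basic PY-NLS consensus scanning,
    in-silico amplicon prediction), and seeded synthetic-data generators
    with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, BiocGenerics, Biostrings, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Normalization, Sequencing
RoxygenNote: 7.3.3
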