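Package: urotag
Title: Iso-Length Restriction-Tag Microbiome Profiling and Paired Urobiome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Species-level taxonomic profiling of low-biomass microbiome
    samples from iso-length type IIB restriction-enzyme tags (BcgI), with a
    G-score false-positive screen and two-pass abundance estimation against
    species-specific tag databases, followed by a paired two-group analysis
    stack: alpha and beta diversity with PCoA and PERMANOVA, paired Wilcoxon
    differential-abundance tables, linear-discriminant effect sizes,
    Spearman correlation networks, and random-forest marker selection with a
    probability-of-disease (POD) index.  A synthetic-data module generates
    taxonomies, genomes, paired community designs, and reads with known
    ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    pROC,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
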