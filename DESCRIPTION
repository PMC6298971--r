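Package: pulpredict
Title: Polysaccharide Utilization Locus Detection, Substrate Prediction and
    SusC/D Expression Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects polysaccharide utilization loci (PULs) in flavobacterial
    genomes from consensus CAZyme and SusC/SusD annotations, classifies their
    polysaccharide substrates with a declarative rule engine, builds
    substrate-labelled SusC/D identity trees, places environmental SusC/D
    homologs onto the labelled reference set, and turns metaproteomic
    spectral counts into %NSAF-based temporal substrate-expression profiles.
    A seeded synthetic-data module generates genomes with planted PULs and
    metaproteome count tables so the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    phangorn,
    dplyr,
    tibble,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
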