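Package: mustsig
Title: Vineyard-Site Signatures in Grape-Must Microbiomes and Fermentation
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for asking whether grape-must microbial DNA profiles and
    wine-fermentation transcriptomes carry vineyard-site, region, and vintage
    signatures, and whether DNA abundance predicts RNA activity. Implements
    compositional data analysis (centered log-ratio transform, Aitchison
    distance, core-microbiome detection, alpha diversity), permutation-based
    community statistics (ANOSIM, PERMANOVA, Mantel tests with exhaustive
    small-n enumeration), DNA-RNA concordance regression per organism and
    timepoint, and consensus random-forest signature extraction across seeds
    with casewise permutation importance and leave-one-vintage-out validation.
    A hierarchical Dirichlet-multinomial study generator produces complete
    synthetic studies (amplicon counts, tagged 3' transcript counts, must
    chemistry, spatially autocorrelated climate) with a ground-truth record
    for power and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    ranger,
    vegan,
    permute,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
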