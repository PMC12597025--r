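Package: betadev
Title: Null-Model Beta-Deviation Analysis of Host-Associated Microbiome
    Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify the relative roles of niche selection and
    ecological drift in host-associated bacterial community assembly along
    an immigration (inoculum-density) gradient.  Provides abundance-table
    transformations (family aggregation, focal-taxon subsetting,
    relativization, qPCR copy-number scaling), Hill diversity numbers,
    Bray-Curtis dissimilarity, beta-diversity as multivariate dispersion
    (distance to the group spatial median in principal-coordinate space,
    with square-root and small-sample bias adjustments), and an
    abundance-constrained null model that preserves each sample's observed
    richness and community size to compute standardized beta-deviations
    (SES).  A synthetic-experiment generator simulates colonization,
    within-host selection and demographic drift across larval stages so
    the full pipeline can be exercised and calibrated without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
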