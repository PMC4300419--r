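Package: biosol
Title: Predicting Apparent Drug Solubility in Biorelevant Intestinal Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling apparent solubility of lipophilic drugs in
    fasted-state simulated intestinal fluid (FaSSIF) and aspirated human
    intestinal fluid (HIF). Ships a curated dataset of 86 drugs with apparent
    solubility in phosphate buffer pH 6.5, FaSSIF and HIF, and implements a
    complete chemometric workflow: descriptor preprocessing (signed cube-root
    transform, normality screening, autoscaling), NIPALS partial least squares
    with cross-validated Q2, variable importance to projection (VIP), Hotelling
    T2 and distance-to-model (DModX) outlier diagnostics, response-sorted
    train/test splitting with outlier relocation, VIP-guided greedy backward
    descriptor elimination, augmentation with experimentally determined
    properties, consensus averaging of independent predictors, and
    lipophilicity-stratified correlation analyses between dissolution media.
    A seeded synthetic-data generator with known latent structure supports
    end-to-end validation without proprietary descriptor software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
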