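Package: gutbraintools
Title: Analysis Toolkit for DSS-Colitis Gut-Brain Axis Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for preclinical gut-brain axis studies built
    around the dextran sulfate sodium (DSS) colitis mouse model. Implements
    composite disease-activity-index (DAI) scoring from daily animal
    observations, least-squares cosinor rhythmometry of clock-gene qPCR time
    series, gadolinium tracer signal-enhancement kinetics with
    repeated-measures mixed-model ANOVA, KCl-evoked neurotransmitter overflow
    statistics from four-fraction superfusion assays, label-free CSF
    proteomics differential expression with Benjamini-Hochberg FDR and
    offline Fisher gene-set enrichment, and a statistics toolbox covering
    normality-gated two-sample tests, eta-squared effect sizes, and exact
    noncentral-t sensitivity power analysis. Seeded synthetic-data generators
    emulate every input structure so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    emmeans,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
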