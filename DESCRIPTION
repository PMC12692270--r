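Package: splitsig
Title: Subtype-Specific Somatic Driver Discovery by Cohort-Split Randomisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing the somatic mutation landscape of two tumour
    subtypes from annotated variant tables. Implements a functional-impact-bias
    permutation test and a length-aware binomial recurrence test for per-gene
    driver significance with Benjamini-Hochberg FDR control, a cohort-split
    randomisation test that builds an empirical null for subtype-specific
    driver candidates from repeated balanced relabellings, pathway-level
    impact-bias scoring with shared/specific set comparison, recurrent-residue
    hotspot calling and protein-domain mutational clustering, copy-number
    burden summaries (fraction of genome altered, including copy-neutral LOH),
    and 2^-ddCt relative quantification of qPCR data with geometric-mean
    housekeeping normalisation. A synthetic-cohort simulator with planted
    drivers, hotspots, copy-number events and expression fold changes makes
    every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glue,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
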