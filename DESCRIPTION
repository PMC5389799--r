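Package: ecflux
Title: Neurotransmitter Flux from 13C Enrichment of Extracellular
    Glutamate and Glutamine Measured by GC-MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the flux of neurotransmitter glutamate and its
    precursor glutamine from the brain extracellular fluid, using the
    13C enrichment of microdialysate glutamate/glutamine measured by
    gas-chromatography mass-spectrometry (selected ion monitoring)
    during [2,5-13C]glucose infusion. Converts raw light/heavy ion peak
    areas to biological fractional enrichment with natural-abundance
    heavy-isotope correction, isolates positional C5 enrichment with a
    time-dependent label-scrambling model, models the microdialysis
    fraction schedule (pooling, dead-time correction, baseline
    normalization), estimates per-subject enrichment rates by least
    squares, and compares experimental groups with one-way ANOVA plus
    Scheffe and Tukey-Kramer post-hoc tests. A synthetic-cohort
    generator emulates control, infrequently seizing and frequently
    seizing kainate-model rat groups so the full pipeline is testable
    end-to-end by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
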