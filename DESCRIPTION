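Package: snowfloc
Title: Evolutionary Dynamics of Clonal and Aggregative Multicellular Life Cycles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models and statistics for contrasting clonal ("snowflake") and
    aggregative ("floc") multicellular life cycles evolving under daily cycles
    of batch growth and settling selection. Provides an analytic
    extinction-probability theory for rare mutant lineages passing through a
    group-selection bottleneck (exact hypergeometric form and large-population
    exponential approximation), a stochastic simulator of mutant-lineage fate
    across repeated rounds of growth, group formation and size-weighted
    settling selection, group-level phenotype statistics (settling rate from
    image stacks, flocculation efficiency, biomass-weighted mean group size),
    competition-derived fitness and assortment statistics, and a bootstrap
    test comparing observed mutation-class spectra against a simulated neutral
    null on an annotated genome. A synthetic-data generator supplies every
    input with known ground truth, so all estimators can be validated by
    parameter recovery without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
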