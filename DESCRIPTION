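Package: xritrace
Title: Decoding Gene-Expression Histories from Expression Recording Islands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reading out gene-expression histories recorded along
    expression recording islands (XRIs): intracellular, bidirectionally growing
    self-assembled protein filaments whose epitope-tagged monomers preserve the
    temporal order of expression. The package measures per-channel intensity
    profiles along filament centerlines in multichannel fluorescence images,
    converts the constitutive-tag cumulative line integral into a calibratable
    molecular clock, decodes induced-tag signals by derivative with respect to
    that clock with an optimal split-point search, estimates expression onset by
    linear extrapolation of the rising phase, builds monotone time calibrations
    from timed-induction cohorts, and aggregates cohorts with rank-based group
    statistics. A stochastic forward simulator of filament growth and a
    synthetic multichannel microscopy renderer provide ground truth so that
    every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    tiff,
    pracma,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
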