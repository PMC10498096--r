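Package: trumpetr
Title: Trumpet Plots of Variant Effect Size Across the Allele Frequency Spectrum
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for visualizing the relationship between allele frequency
    and effect size in genetic association studies. Reads and validates GWAS and
    exome summary-statistics tables, harmonizes records to a minor-allele or
    positive-effect orientation, selects independent significant variants by
    greedy linkage-disequilibrium clumping or approximate conditional/joint
    stepwise analysis, computes analytic statistical-power curves from the
    one-degree-of-freedom non-central chi-square model, and renders the
    "trumpet" scatter of effect size against log10 allele frequency with power
    curve overlays, as static figures or self-contained interactive HTML.
    Includes a synthetic summary-statistics and cohort simulator with a
    frequency-dependent effect-size architecture and copula-based
    linkage-disequilibrium blocks, so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
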