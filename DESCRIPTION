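Package: elastidms
Title: Latent Mutant Effects from Bulk-Competition Deep Mutational Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates effective selection coefficients of codon substitutions
    from bulk-competition sequencing count time series, fits the hyperbolic
    expression-growth elasticity function, inverts fitness measurements to
    per-molecule function across a ladder of promoter strengths, quantifies
    expression-by-mutation epistasis, and simulates competition trajectories
    under constant or linearly increasing expression. Includes a synthetic-data
    generator that produces mutant libraries with known true function, count
    tables with multinomial sequencing noise, growth curves, and expression
    time courses, so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    ggplot2,
    generics,
    minpack.lm,
    readr,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
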