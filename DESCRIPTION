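Package: biofilmtfm
Title: Colony Spreading and Traction Force Microscopy on Soft Substrates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative image-analysis pipeline for time-lapse studies of
    bacterial colonies spreading over soft elastic substrates. Provides
    seeded synthetic generators for bright-field colony stacks and
    fluorescent-bead stacks with exact ground truth; colony boundary
    detection with circular-arc fitting and radial expansion velocimetry;
    windowed cross-correlation particle image velocimetry (PIV) with
    stage-drift correction and divergence-field analysis; and regularized
    elastostatic traction reconstruction on a linear elastic half-space,
    with surface strain and stress summaries. All user-facing results are
    tidy tibbles designed for piped workflows, with ggplot2 helpers for
    the standard figure types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    grDevices,
    tiff,
    EBImage,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
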