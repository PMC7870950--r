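Package: ganglia
Title: Hierarchical Contextual Detection and Diagnostic Triage of
    Colonic Ganglion Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects ganglion cells in H&E-stained colon histology images
    using a hierarchical contextual analysis: anatomical-layer constraints
    veto candidates outside the submucosa and muscularis propria, and
    neighbourhood evidence (clustering, Schwann-like companions, vessel
    proximity) iteratively re-scores the survivors.  On top of the detector
    it implements a diagnostic triage layer for Hirschsprung's disease
    work-ups: ranked sets of three candidate images per case, a case-level
    AI score from the top three sets, pathologist 1-5 scoring, expert and
    non-expert classification rules with a Doubt/consultation route, and
    cell-level and cohort-level statistics.  A seeded synthetic colon-wall
    generator (layered mucosa to serosa, mature and immature ganglion
    cells, mimics, vessels) makes the whole pipeline testable end to end
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
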