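Package: sectorscan
Title: Surface Point-Cloud Extraction from Motion-Tracked Glove Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Extracts the on-surface subset of a stream of 6-DoF position
    samples produced by a sensing glove moved over a solid object. Raw
    samples are rigid-frame compensated against an object-mounted
    reference sensor, binned into solid angular sectors around one or
    more interior reference points, reduced to the closest sample per
    sector (volume minimization), and cleaned by a coarse-sector
    mean-relative outlier rejector. Includes a simulator of glove
    scanning sessions over parametric surfaces (sphere, capped cylinder,
    foot-like composite) with sensor noise, lifted transit motion, gross
    outliers and rigid object motion, plus evaluation tools:
    cloud-to-surface and cloud-to-mesh distances, selectivity curves and
    label-based confusion counts. A command-line entry point drives
    simulate/filter/evaluate/sweep pipelines on CSV sample files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
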