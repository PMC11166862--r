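Package: effcnr
Title: Effective Contrast-to-Noise Ratio Analysis for CT Image Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for task-independent contrast-resolution assessment of
    computed tomography (CT) images. Implements the apparent noise index,
    which quantifies noise magnitude together with noise texture from the
    1/r decay of moving-average-filtered standard deviations; an edge-profile
    model derived from a stochastic differential equation for CT numbers,
    fitted to angle-averaged radial edge profiles of circular inserts to
    yield a sharpness index; and the composite effective CNR, the product of
    contrast and sharpness divided by apparent noise. A synthetic phantom
    generator with controllable noise magnitude, noise correlation and edge
    blur makes every stage testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    tools,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
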