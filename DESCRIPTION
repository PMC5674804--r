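Package: mzlod
Title: Level-of-Detail Serving of LC-MS Point Clouds from mzML
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A backend stack for interactive visualization of LC-MS (MS1)
    maps: a single-pass streaming mzML reader that extracts centroided
    (m/z, retention time, intensity) points with constant memory, a
    hierarchical level-of-detail index that culls sub-threshold noise,
    partitions points into bounding boxes and samples each node by
    intensity, viewport queries that return an exact requested number of
    real (never aggregated) data points, an HTTP JSON service exposing
    point and bounds endpoints, and a seeded synthetic MS1 generator
    (isotopic envelopes with Gaussian elution plus noise) so the whole
    stack is testable offline. Includes an mzML writer covering 32/64-bit,
    zlib/uncompressed and indexed/plain dialects, a spectra subsetter and
    a parser-scaling benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    xml2,
    jsonlite,
    httpuv,
    digest,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    curl,
    mzR,
    withr
Config/testthat/edition: 3
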