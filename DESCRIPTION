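Package: logolift
Title: Reconstruct Position Weight Matrices from Sequence Logo Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recovers the position weight matrix (PWM) behind a DNA
    sequence logo from a raster image of the logo (PNG, JPEG or GIF).
    Pixels are assigned to six reference colors by nearest-centroid
    classification, axes are detected from long black runs, letter
    columns are segmented by X-projection peak voting, and per-column
    probabilities are obtained by inverting the Shannon information
    content of the letter stack. Includes a sequence-logo renderer
    with recorded ground-truth geometry so reconstruction accuracy can
    be verified by round-trip on synthetic logos, writers and readers
    for CSV, MEME and enologos-style motif files, a JASPAR PFM reader,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    generics,
    ggplot2,
    jpeg,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
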