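Package: histomux
Title: Multicolor Immunofluorescence Single-Cell Analysis of Histone Modifications
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A reusable pipeline for multicolor immunofluorescence single-cell
    analysis of histone modification levels: seeded synthetic population and
    image-field generation, Hoechst-based nuclear segmentation with edge and
    mitotic exclusion, background-subtracted per-nucleus intensity
    quantification, order-statistic Hoechst normalization, replicate Pearson
    correlation profiling against DNA content and an S-phase reference mark,
    three-group cell-cycle classification of modifications,
    transfection-gated demethylase target calling, and plate-based inhibitor
    screening with serial-dilution response summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
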