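Package: hicbridge
Title: Read, Write, Convert and Balance Hi-C Contact Matrices in Cooler and .hic Formats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for Hi-C interaction matrices stored in the Cooler
    family of HDF5 containers (.cool, .mcool, .scool) and in the .hic binary
    format. Provides native readers and writers for both families (.hic
    version 8 writing, versions 8 and 9 reading), one uniform pixel-selector
    query interface over both backends with raw, balanced, expected and
    observed/expected counts, ingestion of 4DN pairs and interaction text
    with out-of-core aggregation, k-way file merging, coarsening and
    multi-resolution zoomify ladders, lossless format conversion, iterative
    correction (ICE) matrix balancing, distance-decay expected profiles, a
    seeded synthetic-data generator for contact maps with realistic distance
    decay, and a command-line interface mirroring the library operations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rhdf5,
    data.table,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
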