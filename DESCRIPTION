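Package: blockcor
Title: Memory-Budgeted Blocked Computation of All Pairwise Pearson
    Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes all N(N-1)/2 pairwise Pearson correlation
    coefficients among the rows of a voxels-by-timepoints matrix and
    stores them as a single condensed array in row-major upper-triangle
    order. The computation is out-of-core: rows are mean-centered and
    scaled to unit norm so correlation reduces to a dot product, and the
    resulting Gram matrix is evaluated in memory-budgeted blocks, each
    block of voxels multiplied against all not-yet-finished voxels and
    its strictly-upper-triangle entries appended to the condensed array.
    Includes exact bijective mappings between voxel pairs and condensed
    positions, readers for delimited text, raw binary and 4D NIfTI-1
    volumes with optional masks, a random-access on-disk correlation
    store, deterministic synthetic-data generators, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
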