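Package: rnasketch
Title: Template-Based Drawing of RNA Secondary Structure Diagrams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Draws RNA secondary-structure diagrams in consistent,
    reproducible layouts by mapping query sequences onto coordinate
    templates, with dynamic local rearrangement of loops and helices to
    absorb insertions and deletions. Also provides a template-free radial
    layout engine, constrained maximum-base-pair folding of regions not
    covered by a template, pseudoknot and per-nucleotide data-layer
    visualization, Leontis-Westhof base-pair glyphs, a JSON interchange
    format for 2D structure documents, animated SVG morphs between
    alternative structures, and an image-similarity (SSIM) regression
    harness with a small built-in rasterizer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    xml2,
    optparse,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
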