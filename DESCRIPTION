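Package: exsrrf
Title: Super-Resolution Radial Fluctuations and Nanoscale Morphometrics
    for Expansion Microscopy Time Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational side of expansion microscopy with
    super-resolution radial fluctuations (ExSRRF): reading and writing
    fluorescence time stacks, drift correction by subpixel phase-correlation
    registration against the first frame, the SRRF radiality transform with
    temporal averaging and anti-patterning correction, drift-quality metrics
    (offset norms, structural-similarity and mean-squared-error deltas,
    low/high-drift stratification), and ridge-based nanoscale morphometrics:
    Meijering ridge segmentation, ridge density, local spacing by the
    local-thickness (greatest inscribed circle) transform, width and peak
    profiling, nanoruler PSF-separation calls and expansion-factor
    estimation. Seeded generators for blinking-emitter stacks, nanoruler
    pairs, ridge lattices and interdigitating foot-process phantoms allow
    every stage to run on synthetic data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
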