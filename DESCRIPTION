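Package: hexpursuit
Title: Computer-Vision Tracking of Predator-Prey Pursuit on a Hexagonal Grid Board
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tracks a two-agent (predator/prey) pursuit played out on a
    flat-topped hexagonal grid board from overhead video. Provides exact
    hexagonal lattice geometry and nearest-cell lookup, unsupervised
    detection of grid cell centers from board images (Canny edges, closed
    boundary tracing, lattice-consistency repair and pixel/cm calibration),
    per-frame detection of a bright red prey marker (red-dominance mask,
    median filter, circular Hough transform) and a black predator dot
    (binarization, small-component removal, morphological close, circle
    fit), beat-synchronized trajectory formation by snapping detections to
    grid centers, generators for predictable (hex-quantized sinusoid),
    semi-random and random prey movement patterns, a synthetic scene
    renderer with per-frame ground truth for end-to-end validation, and the
    study-level statistics: repeated-measures one-way ANOVA with
    Greenhouse-Geisser correction, eta squared, and Bonferroni-corrected
    paired comparisons with Cohen's d.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
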