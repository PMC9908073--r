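Package: CalciumStream
Title: Causal Real-Time Processing and Decoding of Miniscope Calcium Imaging Streams
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale implementation of a causal, real-time miniscope
    one-photon calcium imaging pipeline: rigid FFT-based motion stabilization
    against a fixed reference template, morphological background removal,
    ROI pixel-mask calcium trace extraction (contour-based and contour-free
    tile mosaics) with drop filtering and threshold spike inference,
    Gray-code (error-correcting output code) linear population decoding of
    position on a circularized linear track, binary-tree behavior
    classification with causal majority smoothing, evaluation statistics
    (distance error, hit rate, spatial tuning similarity, motion-artifact
    scores, event sensitivity and F-scores with shuffle nulls), and a
    closed-loop feedback latency budget model. Includes a synthetic-session
    generator that renders place-cell populations, indicator decay dynamics,
    scripted image motion, and sensor noise with full ground truth, so every
    stage is testable end to end without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    e1071,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, CellBasedAssays, Neuroscience, Visualization
RoxygenNote: 7.3.3
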