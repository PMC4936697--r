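Package: iblopt
Title: Instance-Based Learning Model of the Sugar Factory Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ACT-R style instance-based learning model of the Sugar
    Factory dynamic decision-making task, together with a continuously
    differentiable (smoothed) reformulation and tools for parameter
    estimation. Provides the declarative-memory activation mathematics
    (base-level learning, partial matching, thresholded retrieval), the
    turn-based factory environment, reproducible pseudo-random input
    streams, grid sweeps over the retrieval-threshold and similarity
    weighting parameters, and derivative-free and heuristic optimization
    drivers for fitting the model to human reference performance or
    maximizing its score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nloptr,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
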