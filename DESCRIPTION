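Package: grnibench
Title: Benchmarking and Application of Gene Regulatory Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates benchmark gene regulatory networks and steady-state
    expression data under Hill kinetics (wild-type, per-gene knockdown and
    multifactorial perturbation designs), runs eight unsupervised network
    inference methods (relevance networks, CLR, ARACNE, MRNET, PCIT,
    correlation, soft-thresholded correlation, tree-ensemble regression) and
    a supervised per-regulator SVM method, scores predictions against gold
    standards by tie-aware AUC with systematic parameter sweeps, and compares
    condition-specific networks to detect regulator switching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
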