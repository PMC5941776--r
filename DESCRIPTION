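Package: scmhand
Title: Structural Co-Occurrence Analysis of Handwriting Exams for
    Parkinson's Disease Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify tremor in spiral and meander handwriting
    exams by measuring the similarity between the printed exam template
    and the patient's pen trace. Exams are segmented with morphological
    operators into template and trace layers, a two-image Structural
    Co-occurrence Matrix (SCM) is built between pixel-aligned grayscale
    layers, and eight scalar SCM attributes (correlation, inverse
    difference moment, entropy, chi-square distance and ratio, mean
    absolute difference ratio, Kullback-Leibler divergence, complementary
    absolute difference) are extracted alongside nine classical
    radius-profile attributes (RMS radial deviation, mean relative
    tremor, and related statistics). Subjects are classified with
    Gaussian Naive Bayes, RBF support vector machines, and a supervised
    Optimum-Path Forest under a repeated stratified-split protocol. A
    parametric synthetic-exam generator renders labeled template/trace
    images with a controllable tremor model so the full pipeline can be
    exercised and validated without access to clinical scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
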