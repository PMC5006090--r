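Package: discoseg
Title: Discourse Segment and Experiment-Type Classification for Results Sections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for mining the Results sections of molecular-biology
    articles: clause-level segmentation of narrative text, classification of
    clauses into seven epistemic discourse types (fact, hypothesis, problem,
    goal, method, result, implication) with a linear-chain conditional random
    field and a one-vs-all support vector machine baseline, linkage of
    narrative paragraphs and figure-caption sentences to subfigure-level
    experiments, tf.idf nearest-centroid classification of experiment type
    (PSI-MI / assay codes), confusion-matrix evaluation with support-weighted
    F1 and a most-frequent-class baseline, and a seeded synthetic-corpus
    generator with the statistical structure the classifiers assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
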