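Package: urbanbias
Title: Urban Scaling Models of City-Level Implicit Bias
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling how city population size, demographic
    diversity, and residential racial segregation jointly shape average
    implicit bias levels across cities. Implements a heterogeneous-mixing
    urban scaling model coupled to a power-law learning curve, four aspatial
    residential segregation indices (mean deviance, dissimilarity, Gini,
    correlation ratio), a two-stage log-log OLS inference procedure with
    learning-rate estimation and variance decomposition, split-half noise
    ceiling estimation, per-city Granger temporal-precedence summaries, and a
    synthetic-city generator that emulates tract-level census structure so
    the full pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
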