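Package: richlazy
Title: Rich Versus Lazy Learning and Orthogonal Task Geometry in Small ReLU Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how the initial weight scale of a small
    feedforward ReLU network controls its learning regime (rich versus lazy)
    on a two-context blob-classification task, and for quantifying the
    resulting representational geometry. Provides the synthetic task and
    pattern generators, analytic-gradient SGD training with L2 and auxiliary
    RDM-loss variants, representational similarity analysis (model RDMs,
    z-scored RDM regression, a six-parameter compression/rotation/offset
    geometry model, permutation inference), embedding-dimensionality and
    truncated-SVD readout analyses, unit-level gating diagnostics
    (task-specific/agnostic classification, context-weight correlations,
    ablation, congruency), a psychophysical choice model with behavioral
    geometry fits, and a hand-wired four-unit recurrent gating model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
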