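Package: retrocue
Title: Simulation and Inference for Three-Phase Retro-Cue Memory EEG Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing combined working-memory /
    long-term-memory EEG experiments built around a retro-cue paradigm with
    three phases (encoding, working memory, retrieval). Provides exact
    trial scheduling with condition assignment and probe bookkeeping, a
    synthetic epoched-EEG and behaviour generator with controllable effect
    sizes and 1/f spatially correlated noise, minimal EEG preprocessing
    (windowed-sinc FIR filtering, baseline correction, automated epoch
    rejection), cluster-based permutation statistics for event-related
    potential contrasts, linear-discriminant location decoding within and
    across task phases with balanced folds and super-trial averaging, and a
    behavioural statistics battery (repeated-measures ANOVA with
    Greenhouse-Geisser correction, Friedman test with Kendall's W, paired
    tests with Cohen's d_av, Wilcoxon signed-rank, Benjamini-Hochberg FDR,
    and JZS Bayes factors).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    nortest,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
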