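Package: retrocue
Title: Simulation and Analysis of Cross-Modal Retro-Cueing Detection Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing speeded yes/no detection
    experiments in which a lateralized auditory cue precedes or follows a
    near-threshold visual target (pre- and retro-cueing at signed
    stimulus-onset asynchronies). Provides a synthetic experiment generator
    with a signal-detection observer, trial exclusion and analysis-cell
    assignment, d-prime sensitivity analysis with repeated-measures ANOVA
    (Greenhouse-Geisser correction, generalized eta squared) and bootstrap
    contrasts, median response-time and inverse-efficiency analyses, the
    shifted-Wald (shifted inverse-Gaussian) response-time distribution with
    exact sampling and an Euler first-passage simulator, per-cell
    maximum-likelihood fitting of its drift rate, decision threshold and
    non-decision time, and a decile-residual goodness-of-fit battery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
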