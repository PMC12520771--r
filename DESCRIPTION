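Package: loudreg
Title: Regression-to-the-Mean Analysis of 2AFC Loudness Judgements
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for two-alternative
    forced-choice (2AFC) loudness discrimination experiments studying
    regression to the mean sound level. Provides seeded trial-schedule
    generators for block-wise method-of-constant-stimuli sessions and
    context-adaptation sessions, a central-tendency generative observer
    whose percept is a weighted average of the stimulus and a running
    anchor, cumulative-Gaussian psychometric fitting with PSE extraction
    and catch-trial exclusion, slope-based adaptation indices with
    half-split and context contrasts, and the matching inferential
    statistics (mixed within-between ANOVA with eta squared, pooled
    t-tests with Cohen's d, and JZS Bayes factors), plus a one-command
    replication and parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
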