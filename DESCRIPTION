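Package: srflex
Title: Explainable Lexicon-Based Suicide-Risk Modelling for Crisis Chat Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transparent, theory-driven analysis of suicide risk in
    text-based crisis helpline conversations. A phrase lexicon of psychological
    constructs (hopelessness, loneliness, previous suicide attempt, ...) is
    compiled to deterministic word-boundary matchers and applied to
    speaker-tagged chat sessions, yielding per-category frequency features with
    span-level explanations. Multivariable logistic regression converts the
    features into odds ratios with Wald 95% confidence intervals, optionally
    stratified by gender or age group, and temporal trajectories of each
    construct's effect are traced across nested chat prefixes (20%-100% of
    help-seeker text). Includes Hosmer-Lemeshow calibration, held-out
    classification metrics (precision/recall/F-beta, midrank ROC-AUC),
    inter-rater agreement (Cohen and Fleiss kappa), and a synthetic chat-corpus
    generator with planted phrase counts and a known logistic ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    stringi,
    tibble,
    tools,
    utils
Suggests:
    ggplot2,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
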