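Package: querywatch
Title: Adverse Drug Reaction Signal Detection from Web Search Query Logs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects candidate adverse drug reactions (ADRs) from aggregated
    web-search behaviour. Implements the query-log reaction score (QLRS), a
    Pearson chi-square statistic on symptom-query counts before and after each
    user's first search for a drug, normalised against users who never searched
    for it; disproportionality comparators for spontaneous-report databases
    (raw counts, DuMouchel's empirical Bayes geometric mean, the Bayesian
    information component); rank-correlation comparison with Fisher-z
    meta-analytic pooling; greedy identification of the most discordant ADRs
    with temporal-onset analysis; a residual-regression method for drug-pair
    interaction ADRs; and a seeded synthetic query-log simulator with planted
    ADR effects, onset delays and acuteness-biased reporting for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
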