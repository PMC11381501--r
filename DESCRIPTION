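Package: hearcommand
Title: Scoring and Psychometric Validation of the HEAR-COMMAND ICF-Based
    Hearing Questionnaire
Version: 0.1.0
Authors@R:
    person("HEAR-COMMAND", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the HEAR-COMMAND instrument, a 90-item
    patient-reported outcome questionnaire grounded in the WHO
    International Classification of Functioning, Disability and Health
    (ICF) Core Sets for Hearing Loss.  Provides the canonical item bank
    (ICF domains and categories, construct labels, score-group
    memberships, facilitator polarity, filter-question gating), response
    coding with non-gradable categories, the three normalized outcome
    scores (hearing-related, non-hearing-related, speech perception),
    pure-tone-average hearing-loss classification and score-based
    disability degrees, the full psychometric validation battery
    (descriptives with floor/ceiling effects, Cronbach's alpha,
    Mann-Whitney U, KMO, Bartlett's sphericity, principal-axis factoring
    with Promax rotation), and a latent-trait synthetic cohort generator
    for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
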