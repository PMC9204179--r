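Package: pvforum
Title: Pharmacovigilance Analysis of Patient Forum Posts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance analyses of patient
    forum posts: deduplication, spam and relevance filtering, and name
    masking of raw posts; dictionary-based mapping of adverse-event
    verbatims to preferred terms with hierarchy roll-up; quarterly
    frequency trends of adverse-event discussions among drug-mentioning
    posts; an empirical-Bayes gamma-Poisson shrinker (EBGM/EB05/EB95)
    for disproportionality analysis of spontaneous-report tables;
    longitudinal author-linked dossiers scored with a configurable
    complexity-indicator registry and medical-insight coverage reports;
    and naive Bayes ranking of adverse-event posts with follow-up case
    selection and engagement metrics. A synthetic-data module generates
    forum corpora, labeled training posts, and simulated report tables
    with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    stringi
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
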