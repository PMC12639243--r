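Package: nhanessnap
Title: Offline Snapshot Building, Metadata, QC and Design-Based Estimation
    for NHANES-Style Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for managing complex-survey data releases organised the way
    the Continuous NHANES is: per-cycle data tables distributed with HTML
    codebook documentation. Parses codebook pages and release manifests into
    relational metadata, builds versioned snapshot stores with raw, translated
    and metadata namespaces, translates coded categorical values to their
    character labels, analyses questionnaire skip logic to separate structural
    missingness from item nonresponse, runs cross-cycle consistency checks
    (label drift, level-case variants, unit changes, variable-name reuse,
    presence gaps), and computes design-based subgroup means with Taylor
    linearized standard errors and confidence intervals. A deterministic
    fixture generator emulates multi-cycle releases, including injectable
    inconsistencies, so every component is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    foreign,
    haven,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
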