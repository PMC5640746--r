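Package: carenets
Title: Mental-Health Service Networks and Patient-Level Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the structure and composition of
    mental-health service referral networks relate to patient-level
    continuity of care and social integration. Builds binary directed
    clinical-contact networks from ordinal tie surveys (with the
    often-only and full-matrix sensitivity variants), computes a suite of
    network-level exposures (composition, index of dissimilarity, density,
    Freeman in-degree centralization, clustering, reciprocity, Coleman
    homophily indices), scores patient outcomes (ACSS-MH continuity,
    SIX social integration), and fits bivariate and stepwise
    random-intercept regressions linking network exposures to outcomes,
    reporting standardized coefficients or odds ratios, network-level
    intra-class correlations, and AIC. A synthetic-study generator with
    tunable density, homophily, centralization and planted outcome
    effects makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    MASS,
    igraph,
    yaml
Suggests:
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
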