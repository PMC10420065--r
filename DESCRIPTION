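Package: endosel
Title: Projection-Predictive Biomarker Selection for Endoscopic Disease
    Activity in Pediatric Crohn's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies a minimal set of noninvasive biomarkers predicting
    endoscopically graded mucosal inflammation (remission, mild, moderate,
    severe) in pediatric Crohn's disease. Fits a Bayesian cumulative-logit
    reference model with a regularized horseshoe prior on population-level
    coefficients and patient-level random intercepts, performs
    projection-predictive feature selection on the latent scale with a
    cross-validated forward search, scores six rule-based pediatric disease
    activity indices from config-driven tables and compares their predictive
    probabilities against the selected submodel, and turns C-reactive protein
    and fecal calprotectin measurements into category probabilities for new
    visits. A seeded synthetic cohort generator reproduces the statistical
    structure of the target data so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    coda,
    jsonlite,
    rjags,
    splines,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
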