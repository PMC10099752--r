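Package: trajprofile
Title: Developmental Trajectory Profiles and Adolescent Diagnostic Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how childhood temperamental, emotional and
    behavioral questionnaire measures relate to clinically registered mood and
    anxiety ("emotional") disorders in adolescence. Implements scale scoring
    with proration and ordinal (polychoric) Cronbach's alpha; logistic
    association screens with mother-clustered Huber-White standard errors and
    Benjamini-Hochberg false-discovery-rate control; parallel-process linear
    latent growth models estimated by full-information maximum likelihood;
    latent profile analysis that embeds the growth processes alongside
    cross-sectional symptom scales; and a manual 3-step maximum-likelihood
    estimator of profile-specific odds of a distal binary diagnosis with
    classification-error correction. A synthetic cohort generator emulates the
    measurement design of a large pregnancy cohort linked to a patient
    registry (latent developmental classes, sibling clustering within mothers,
    wave attrition, ICD-10 coded outcomes) so the full pipeline runs without
    access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mvtnorm,
    yaml,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
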